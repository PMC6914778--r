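# shared fixtures for the test suite

pair_type1 <- function(prom = "Phsp-16.2")
  reporter_pair(c("ch_green", "ch_red"), c(prom, prom), "I")

pair_type2 <- function()
  reporter_pair(c("ch_green", "ch_red"), c("Phsp-16.2", "Pvit-2"), "II")

# naive double-loop reference for the moment estimators: literal translation
# of the definitions, no shared intermediates with the implementation
naive_correlated_uncorrelated <- function(x, y) {
  n <- length(x)
  sx <- 0; sy <- 0
  for (i in seq_len(n)) { sx <- sx + x[i]; sy <- sy + y[i] }
  mx <- sx / n; my <- sy / n
  su <- 0; sxy <- 0
  for (i in seq_len(n)) {
    su <- su + (x[i] - y[i])^2
    sxy <- sxy + x[i] * y[i]
  }
  c(correlated = (sxy / n - mx * my) / (mx * my),
    uncorrelated = (su / n) / (2 * mx * my))
}

# four-cell, two-ring construction with zero noise: one channel's setpoint
# differs 3-fold between rings, the other's is flat
four_point_cells <- function() {
  data.frame(
    experiment_id = "exp1",
    animal_id = rep(c("an1", "an2"), each = 2),
    ring = rep(c(1L, 2L), 2),
    cell_id = rep(c("int1a", "int2a"), 2),
    nucleus_count = 2L,
    ch_green = c(100, 100, 100, 100),
    ch_red = c(100, 300, 100, 300),
    stringsAsFactors = FALSE)
}

# write a small cells CSV and return its path
write_fixture_csv <- function(lines, dir = tempdir()) {
  path <- tempfile("cells", tmpdir = dir, fileext = ".csv")
  writeLines(lines, path)
  path
}
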