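test_that("moment estimators reproduce hand-computed values", {
  cu <- correlated_uncorrelated(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(cu["uncorrelated"]), 0)
  expect_equal(unname(cu["correlated"]), 1 / 6)  # (14/3 - 4) / 4

  cu <- correlated_uncorrelated(c(1, 3), c(3, 1))
  expect_equal(unname(cu["uncorrelated"]), 0.5)
  expect_equal(unname(cu["correlated"]), -0.25)

  # covariance with a constant is zero
  x <- c(0.4, 1.1, 2.3, 0.9)
  cu <- correlated_uncorrelated(x, rep(mean(x), 4))
  expect_equal(unname(cu["correlated"]), 0)

  expect_error(correlated_uncorrelated(1, 1), "at least 2")
  expect_error(correlated_uncorrelated(c(1, 2), c(0, 0)),
               "invalid normalization")
})

test_that("estimators agree with the naive double-loop reference", {
  set.seed(401)
  for (i in 1:25) {
    n <- sample(2:50, 1)
    x <- exp(rnorm(n)); y <- exp(rnorm(n))
    expect_equal(correlated_uncorrelated(x, y),
                 naive_correlated_uncorrelated(x, y), tolerance = 1e-12)
  }
})

test_that("correlated + uncorrelated equals the mean squared CV on mean-1 data", {
  set.seed(402)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    x <- exp(rnorm(n, sd = 0.4)); y <- exp(rnorm(n, sd = 0.4))
    x <- x / mean(x); y <- y / mean(y)
    cu <- correlated_uncorrelated(x, y)
    cv2 <- function(v) mean((v - mean(v))^2) / mean(v)^2
    expect_equal(unname(cu["correlated"] + cu["uncorrelated"]),
                 (cv2(x) + cv2(y)) / 2, tolerance = 1e-12)
  }
})

test_that("group normalization gives exact mean-1 channels and A values", {
  cells <- data.frame(
    experiment_id = "e1", animal_id = c("a1", "a2"), ring = 1L,
    cell_id = c("int1a", "int1b"), nucleus_count = 2L,
    ch_green = c(2, 4), ch_red = c(1, 2), stringsAsFactors = FALSE)
  nb <- normalize_by_group(cells, c("ch_green", "ch_red"),
                           min_group_size = 2)
  expect_equal(nb$cells$ch_green, c(2 / 3, 4 / 3))
  expect_equal(mean(nb$cells$ch_green), 1)
  expect_equal(nb$gains$A, 0.5)  # mean(red)/mean(green) = 1.5/3

  # per-ring normalization aligns rings with unequal setpoints; pooling not
  fp <- four_point_cells()
  by_ring <- normalize_by_group(fp, c("ch_green", "ch_red"),
                                min_group_size = 2)
  for (r in 1:2)
    expect_equal(mean(by_ring$cells$ch_red[by_ring$cells$ring == r]), 1)
  pooled <- normalize_by_group(fp, c("ch_green", "ch_red"),
                               grouping = "experiment_id",
                               min_group_size = 2)
  expect_false(all(tapply(pooled$cells$ch_red, pooled$cells$ring, mean) == 1))

  # undersized and zero-mean groups are skipped with reasons
  fp$ch_green[fp$ring == 2] <- 0
  nb <- normalize_by_group(fp, c("ch_green", "ch_red"), min_group_size = 2)
  expect_match(nb$skipped$reason, "zero group mean")
  expect_error(
    normalize_by_group(fp[1:2, ], c("ch_green", "ch_red"),
                       min_group_size = 5),
    "minimum group size")
})

test_that("scale invariance: channel gain does not change any eta2 bin", {
  cells <- simulate_cells(default_params("paper_like", "TypeI", seed = 21))
  fit1 <- decompose_noise(cells, pair_type1())
  scaled <- cells
  scaled$ch_red <- scaled$ch_red * 37.5
  fit2 <- decompose_noise(scaled, pair_type1())
  expect_equal(fit2$aggregate, fit1$aggregate, tolerance = 1e-12)
  expect_equal(fit2$gains$A, fit1$gains$A * 37.5, tolerance = 1e-12)
})

test_that("Type I decomposition: null data gives zero bins, intrinsic-only data recovers the closed form", {
  nul <- simulate_cells(default_params("null_no_variation", "TypeI"))
  fit <- decompose_noise(nul, pair_type1())
  expect_equal(max(abs(fit$groups$eta2_gamma)), 0)
  expect_equal(max(abs(fit$groups$correlated)), 0)

  p <- generative_params(n_experiments = 1,
                         n_animals_per_experiment = 2500,
                         sigma_gamma = 0.1, experiment_type = "TypeI",
                         channels = c(ch_green = "Phsp-16.2",
                                      ch_red = "Phsp-16.2"),
                         seed = 77)
  fit <- decompose_noise(simulate_cells(p, keep_truth = FALSE),
                         pair_type1())
  truth <- exp(0.1^2) - 1
  expect_lt(abs(fit$aggregate[["eta2_gamma"]] - truth) / truth, 0.05)
  expect_lt(abs(fit$aggregate[["correlated"]]), 0.005)
})

test_that("Type II decomposition subtracts intrinsic noise and clamps overshoot", {
  cells <- simulate_cells(default_params("paper_like", "TypeII", seed = 23))
  pair <- pair_type2()
  fit <- decompose_noise(cells, pair, gamma = 0.002)
  expect_equal(fit$groups$eta2_P_raw, fit$groups$uncorrelated - 0.002)
  expect_equal(fit$groups$eta2_G, fit$groups$correlated)
  expect_false(any(fit$groups$clamped))

  # a gamma larger than any uncorrelated moment forces clamping to zero
  big <- decompose_noise(cells, pair, gamma = 1)
  expect_true(all(big$groups$clamped))
  expect_true(all(big$groups$eta2_P == 0))
  expect_true(all(big$groups$eta2_P_raw < 0))

  expect_error(decompose_noise(cells, pair), "gamma")
  expect_error(
    decompose_noise(cells, pair,
                    gamma = data.frame(promoter = "Phsp-16.2", ring = 1,
                                       eta2_gamma = 0.1)),
    "Pvit-2")
})

test_that("ring-matched gamma is preferred, across-ring mean is the fallback", {
  gam <- data.frame(promoter = rep(c("Phsp-16.2", "Pvit-2"), each = 2),
                    ring = c(1L, NA, 1L, NA),
                    eta2_gamma = c(0.01, 0.04, 0.03, 0.08))
  cells <- simulate_cells(default_params("null_no_variation", "TypeII"))
  fit <- decompose_noise(cells, pair_type2(), gamma = gam)
  g1 <- fit$groups[fit$groups$ring == 1, ]
  g2 <- fit$groups[fit$groups$ring == 2, ]
  expect_equal(unique(g1$eta2_gamma), (0.01 + 0.03) / 2)  # ring-matched
  expect_equal(unique(g2$eta2_gamma), (0.04 + 0.08) / 2)  # fallback
  expect_true(any(grepl("ring-matched", fit$gamma_source)))
  expect_true(any(grepl("across-ring mean", fit$gamma_source)))
})

test_that("gamma_lookup feeds a Type I fit into a Type II decomposition", {
  fitI <- decompose_noise(
    simulate_cells(default_params("paper_like", "TypeI", seed = 3)),
    pair_type1())
  lk <- gamma_lookup(fitI)
  expect_setequal(names(lk), c("promoter", "ring", "eta2_gamma"))
  expect_identical(sum(is.na(lk$ring)), 1L)  # one across-ring fallback row
  expect_equal(lk$eta2_gamma[is.na(lk$ring)], mean(fitI$groups$eta2_gamma))
  expect_error(gamma_lookup(decompose_noise(
    simulate_cells(default_params("paper_like", "TypeII", seed = 3)),
    pair_type2(), gamma = 0.002)), "Type I")
})

test_that("pooling rings inflates pathway noise on the 4-point construction", {
  fp <- four_point_cells()
  res <- pooled_vs_grouped(fp, pair_type2(), gamma = 0, min_group_size = 2)
  expect_equal(res$grouped_eta2_P, 0)
  # brute force: x = 1,1,1,1; y = 0.5,1.5,0.5,1.5 after pooled
  # normalization; uncorrelated = mean((x-y)^2)/2 = 0.125
  expect_equal(res$pooled_eta2_P, 0.125)
  expect_gt(res$inflation, 0)

  # equal setpoints: pooled and grouped agree within Monte-Carlo error
  sp <- data.frame(promoter = rep(c("Phsp-16.2", "Pvit-2"), each = 4),
                   ring = rep(1:4, 2), setpoint = 500)
  p <- default_params("paper_like", "TypeII", seed = 41, setpoints = sp,
                      n_experiments = 1, n_animals_per_experiment = 200)
  res <- pooled_vs_grouped(simulate_cells(p), pair_type2(), gamma = 0)
  expect_lt(abs(res$inflation), 0.01)

  # single ring degenerates with a warning
  expect_warning(
    pooled_vs_grouped(fp[fp$ring == 1, ], pair_type2(), gamma = 0,
                      min_group_size = 2),
    "single ring")
})

test_that("increasing pathway or capacity dispersion increases the recovered bin", {
  fit_for <- function(sP, sG) {
    p <- generative_params(n_experiments = 1,
                           n_animals_per_experiment = 500,
                           sigma_G_cell = sG, sigma_P = sP,
                           experiment_type = "TypeII", seed = 53)
    decompose_noise(simulate_cells(p, keep_truth = FALSE), pair_type2(),
                    gamma = 0)
  }
  lo <- fit_for(0.05, 0.2); hi <- fit_for(0.30, 0.2)
  expect_gt(hi$aggregate[["eta2_P"]], lo$aggregate[["eta2_P"]])
  glo <- fit_for(0.05, 0.1); ghi <- fit_for(0.05, 0.5)
  expect_gt(ghi$aggregate[["eta2_G"]], glo$aggregate[["eta2_G"]])
})

test_that("combined scatter stacks normalized points with type labels", {
  fitI <- decompose_noise(
    simulate_cells(default_params("null_no_variation", "TypeI")),
    pair_type1())
  fitII <- decompose_noise(
    simulate_cells(default_params("paper_like", "TypeII", seed = 61)),
    pair_type2(), gamma = 0.002)
  sc <- combined_scatter(fitI, fitII)
  expect_identical(nrow(sc), fitI$n_cells + fitII$n_cells)
  # null Type I data sits exactly on the diagonal
  expect_equal(max(abs(sc$x[sc$type == "I"] - sc$y[sc$type == "I"])), 0)

  fitI2 <- decompose_noise(
    simulate_cells(default_params("paper_like", "TypeI", seed = 61)),
    pair_type1())
  sc2 <- combined_scatter(list(fitI2, fitII))
  spread <- tapply(abs(sc2$x - sc2$y), sc2$type, mean)
  expect_gt(spread[["II"]], spread[["I"]])
})

test_that("pearson_r matches hand-computed coefficients and rejects degenerate input", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_error(pearson_r(c(1, 2), c(3, 4)), "at least 3")
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "degenerate input")
})

test_that("compare_bins picks the right test and reports contrasts", {
  # clearly separated bins: significant two-sample t-test
  cmp <- compare_bins(list(gamma = c(0.10, 0.11, 0.09),
                           G = c(0.30, 0.31, 0.29)))
  expect_match(cmp$method, "t-test")
  expect_lt(cmp$p_value, 0.05)
  expect_true(cmp$significant)

  # identical bins: t = 0, p = 1
  cmp <- compare_bins(list(a = c(0.1, 0.2, 0.3), b = c(0.1, 0.2, 0.3)))
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p_value, 1)
  expect_false(cmp$significant)

  # three bins: ANOVA with exactly 3 Tukey contrasts
  cmp <- compare_bins(list(a = c(0.1, 0.12, 0.11), b = c(0.2, 0.21, 0.19),
                           c = c(0.5, 0.52, 0.51)))
  expect_match(cmp$method, "ANOVA")
  expect_identical(nrow(cmp$contrasts), 3L)

  # a non-normal bin routes to the rank-based branch, and that is recorded
  skewed <- c(1, 1.01, 1.02, 1.01, 1, 50)
  cmp <- compare_bins(list(a = skewed, b = skewed + 100))
  expect_match(cmp$method, "Mann-Whitney")
  expect_false(all(cmp$normal))

  expect_error(compare_bins(list(a = c(1, 1, 1), b = c(2, 2, 2))),
               "zero variance")
  expect_error(compare_bins(list(a = c(1, 2))), ">= 2")
})

test_that("study-scale capacity recovery stays within the sampling envelope", {
  # 200 seeded replicates at 3 experiments x 10 animals x 8 cells: the
  # recovered eta2_G lands within +/-30% of the closed-form truth in at
  # least 90% of replicates (envelope set by the estimator's own sampling
  # distribution under the generative model)
  truth <- expected_eta2(default_params("paper_like"))$eta2_G_true
  hits <- vapply(seq_len(200), function(i) {
    cells <- simulate_cells(default_params("paper_like", "TypeII",
                                           seed = 1000 + i),
                            keep_truth = FALSE)
    fit <- decompose_noise(cells, pair_type2(), gamma = 0)
    abs(fit$aggregate[["eta2_G"]] - truth) / truth <= 0.30
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})
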