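test_that("scenario defaults are populated and unknown scenarios are rejected", {
  p <- default_params("null_no_variation")
  expect_s3_class(p, "generative_params")
  expect_identical(
    c(p$sigma_G_animal, p$sigma_G_cell, p$sigma_P, p$sigma_gamma,
      p$sigma_meas),
    rep(0, 5))
  expect_true(all(p$setpoints$setpoint > 0))
  expect_error(default_params("nope"), "paper_like")

  # paper_like: capacity bin dominates intrinsic bin more than ten-fold
  truth <- expected_eta2(default_params("paper_like"))
  expect_gt(truth$eta2_G_true, 10 * truth$eta2_gamma_true)
  # yeast_like triples the intrinsic scale, high_signaling inflates sigma_P
  expect_equal(default_params("yeast_like")$sigma_gamma,
               3 * default_params("paper_like")$sigma_gamma)
  expect_gt(default_params("high_signaling")$sigma_P,
            default_params("paper_like")$sigma_P)
})

test_that("parameter validation rejects invalid settings", {
  expect_error(generative_params(sigma_P = -0.1), "sigma")
  expect_error(generative_params(n_experiments = 0), "counts")
  expect_error(generative_params(
    setpoints = data.frame(promoter = "a", ring = 1, setpoint = -1)), "> 0")
  expect_error(generative_params(
    experiment_type = "TypeI",
    channels = c(ch_green = "Phsp-16.2", ch_red = "Pvit-2")),
    "same promoter")
})

test_that("simulated tables have the study structure and are deterministic", {
  p <- default_params("paper_like", "TypeII", seed = 11)
  cells <- simulate_cells(p)
  expect_identical(nrow(cells), 240L)  # 3 x 10 x 8
  expect_identical(sort(unique(cells$ring)), 1:4)
  expect_true(all(table(cells$animal_id) == 8L))
  # two cells per ring per animal
  expect_true(all(table(cells$animal_id, cells$ring) == 2L))
  expect_identical(simulate_cells(p), cells)

  # counter-based seeding: dropping animals leaves the others untouched
  p5 <- default_params("paper_like", "TypeII", seed = 11,
                       n_animals_per_experiment = 5)
  small <- simulate_cells(p5)
  expect_identical(small,
                   {
                     sub <- cells[cells$animal_id %in% small$animal_id, ]
                     rownames(sub) <- NULL
                     attr(sub, "channels") <- attr(cells, "channels")
                     sub
                   })
})

test_that("null scenario reproduces setpoints exactly", {
  cells <- simulate_cells(default_params("null_no_variation", "TypeII"))
  sp <- default_setpoints()
  for (ch in c("ch_green", "ch_red")) {
    prom <- if (ch == "ch_green") "Phsp-16.2" else "Pvit-2"
    want <- sp$setpoint[match(paste(prom, cells$ring),
                              paste(sp$promoter, sp$ring))]
    expect_identical(cells[[ch]], want)
  }
})

test_that("latent factors follow the sharing rules of the two designs", {
  p1 <- default_params("paper_like", "TypeI", seed = 2)
  c1 <- simulate_cells(p1)
  # G factors and the pathway draw are shared across channels in Type I
  expect_identical(c1$true_P_ch_green, c1$true_P_ch_red)
  expect_false(identical(c1$true_gamma_ch_green, c1$true_gamma_ch_red))
  # G_animal constant within animal
  expect_true(all(tapply(c1$true_G_animal, c1$animal_id,
                         function(v) length(unique(v))) == 1L))

  c2 <- simulate_cells(default_params("paper_like", "TypeII", seed = 2))
  expect_false(identical(c2$true_P_ch_green, c2$true_P_ch_red))

  # keep_truth = FALSE strips the latent columns
  blind <- simulate_cells(p1, keep_truth = FALSE)
  expect_false(any(grepl("^true_", names(blind))))
})

test_that("group means converge to setpoint plus background", {
  p <- generative_params(
    n_experiments = 1, n_animals_per_experiment = 12500,
    cells_per_animal = 8, sigma_G_animal = 0.2, sigma_G_cell = 0.3,
    sigma_P = 0.1, sigma_gamma = 0.05, sigma_meas = 0.03,
    background = c(ch_green = 50, ch_red = 0),
    experiment_type = "TypeII", seed = 99)
  cells <- simulate_cells(p, keep_truth = FALSE)
  sp <- default_setpoints()
  for (r in 1:4) {
    m_g <- mean(cells$ch_green[cells$ring == r])
    m_r <- mean(cells$ch_red[cells$ring == r])
    want_g <- 50 + sp$setpoint[sp$promoter == "Phsp-16.2" & sp$ring == r]
    want_r <- sp$setpoint[sp$promoter == "Pvit-2" & sp$ring == r]
    expect_lt(abs(m_g - want_g) / want_g, 0.01)
    expect_lt(abs(m_r - want_r) / want_r, 0.01)
  }
})

test_that("dropout removes cells without disturbing the kept draws", {
  p0 <- default_params("paper_like", "TypeII", seed = 31)
  p1 <- default_params("paper_like", "TypeII", seed = 31, dropout = 0.2)
  full <- simulate_cells(p0)
  dropped <- simulate_cells(p1)
  expect_lt(nrow(dropped), nrow(full))
  key <- function(d) paste(d$animal_id, d$cell_id)
  expect_true(all(key(dropped) %in% key(full)))
  kept <- full[match(key(dropped), key(full)), ]
  expect_equal(dropped$ch_green, kept$ch_green)
})

test_that("closed-form expectations respond monotonically to the sigmas", {
  base <- default_params("paper_like")
  bump <- function(field, by) {
    q <- base
    q[[field]] <- q[[field]] + by
    class(q) <- "generative_params"
    q
  }
  expect_gt(expected_eta2(bump("sigma_P", 0.1))$eta2_P_true,
            expected_eta2(base)$eta2_P_true)
  expect_gt(expected_eta2(bump("sigma_G_cell", 0.1))$eta2_G_true,
            expected_eta2(base)$eta2_G_true)
  expect_gt(expected_eta2(bump("sigma_gamma", 0.1))$eta2_gamma_true,
            expected_eta2(base)$eta2_gamma_true)
  # all bins are nonnegative, zero in the null scenario
  nul <- expected_eta2(default_params("null_no_variation"))
  expect_identical(unname(unlist(nul)), rep(0, length(nul)))
})
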