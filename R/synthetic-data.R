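#' Generative parameters for synthetic per-cell reporter tables
#'
#' Describes a multiplicative lognormal model of per-cell fluorescence in the
#' intestine of an adult nematode. Each measured intensity is
#'
#' \deqn{I = b + m(promoter, ring) \cdot G_{animal} \cdot G_{cell} \cdot
#'   P(promoter) \cdot \gamma(channel) \cdot \epsilon(channel)}
#'
#' where every latent factor is an independent mean-one lognormal draw:
#' `G_animal` is shared by all cells of an animal (animals differ in overall
#' protein expression capacity), `G_cell` by both channels of a cell,
#' `P` is drawn once per distinct promoter per cell (pathway activation),
#' `gamma` once per reporter copy per cell (intrinsic/allele noise) and
#' `epsilon` once per channel per cell (measurement noise). `m(promoter,
#' ring)` is the ring-specific expression setpoint and `b` an optional
#' additive background. The mean-one convention (`exp(sigma*Z - sigma^2/2)`)
#' makes group mean intensities converge to `setpoint + background` and gives
#' the exact closed-form variance-bin expectations of [expected_eta2()].
#'
#' @param n_experiments number of independent experiments (default 3).
#' @param n_animals_per_experiment animals measured per experiment (default
#'   10).
#' @param cells_per_animal cells measured per animal, spread evenly over
#'   rings 1-4 (default 8, i.e. two per ring).
#' @param sigma_G_animal lognormal scale of the per-animal shared capacity
#'   factor.
#' @param sigma_G_cell lognormal scale of the per-cell capacity deviation
#'   (shared by all channels of a cell).
#' @param sigma_P lognormal scale of per-cell pathway activation (one draw
#'   per distinct promoter per cell).
#' @param sigma_gamma lognormal scale of the per-allele intrinsic factor (one
#'   draw per reporter copy per cell).
#' @param sigma_meas lognormal scale of per-channel multiplicative
#'   measurement noise.
#' @param setpoints data.frame with columns `promoter`, `ring`, `setpoint`
#'   (positive mean intensity, arbitrary units) giving the rigid
#'   cell-fate-specific expression setpoint of each promoter in each ring.
#' @param background named numeric of per-channel additive autofluorescence
#'   offsets (>= 0), or a single value recycled to both channels.
#' @param experiment_type `"TypeI"` (both channels are copies of the same
#'   gene: shared pathway draw, independent allele draws) or `"TypeII"`
#'   (distinct promoters: independent pathway draws).
#' @param channels named character vector mapping channel column name to the
#'   promoter driving it, e.g. `c(ch_green = "Phsp-16.2", ch_red =
#'   "Pvit-2")`.
#' @param dropout per-cell probability that a cell could not be measured
#'   (default 0; in real acquisitions cells in rings two and four are
#'   occasionally lost to the orientation of the intestine).
#' @param seed integer root seed. Draws are seeded per (experiment, animal)
#'   counter so that subsetting animals does not shift the draws of other
#'   animals.
#' @return An object of class `"generative_params"`.
#' @seealso [default_params()], [simulate_cells()], [expected_eta2()]
#' @export
generative_params <- function(n_experiments = 3L,
                              n_animals_per_experiment = 10L,
                              cells_per_animal = 8L,
                              sigma_G_animal = 0,
                              sigma_G_cell = 0,
                              sigma_P = 0,
                              sigma_gamma = 0,
                              sigma_meas = 0,
                              setpoints = default_setpoints(),
                              background = 0,
                              experiment_type = c("TypeII", "TypeI"),
                              channels = NULL,
                              dropout = 0,
                              seed = 1L) {
  experiment_type <- match.arg(experiment_type)
  counts <- c(n_experiments = n_experiments,
              n_animals_per_experiment = n_animals_per_experiment,
              cells_per_animal = cells_per_animal)
  if (any(!is.finite(counts)) || any(counts < 1))
    stop("all counts must be >= 1")
  sigmas <- c(sigma_G_animal = sigma_G_animal, sigma_G_cell = sigma_G_cell,
              sigma_P = sigma_P, sigma_gamma = sigma_gamma,
              sigma_meas = sigma_meas)
  if (any(!is.finite(sigmas)) || any(sigmas < 0))
    stop("all sigma parameters must be finite and >= 0")
  if (!is.data.frame(setpoints) ||
      !all(c("promoter", "ring", "setpoint") %in% names(setpoints)))
    stop("'setpoints' needs columns promoter, ring, setpoint")
  if (any(setpoints$setpoint <= 0)) stop("all setpoints must be > 0")
  if (is.null(channels)) {
    proms <- unique(setpoints$promoter)
    channels <- if (experiment_type == "TypeI") {
      c(ch_green = proms[1], ch_red = proms[1])
    } else {
      if (length(proms) < 2)
        stop("TypeII defaults need at least two promoters in 'setpoints'")
      c(ch_green = proms[1], ch_red = proms[2])
    }
  }
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("'channels' must be a named vector: channel column -> promoter")
  if (experiment_type == "TypeI" && length(unique(channels)) != 1L)
    stop("TypeI requires both channels to reference the same promoter")
  if (experiment_type == "TypeII" && length(unique(channels)) < 2L)
    stop("TypeII requires distinct promoters across channels")
  if (!all(channels %in% setpoints$promoter))
    stop("every channel promoter needs setpoints; missing: ",
         paste(setdiff(channels, setpoints$promoter), collapse = ", "))
  if (length(background) == 1L)
    background <- stats::setNames(rep(background, length(channels)),
                                  names(channels))
  if (any(background < 0)) stop("background offsets must be >= 0")
  if (dropout < 0 || dropout >= 1) stop("'dropout' must be in [0, 1)")
  structure(
    list(n_experiments = as.integer(n_experiments),
         n_animals_per_experiment = as.integer(n_animals_per_experiment),
         cells_per_animal = as.integer(cells_per_animal),
         sigma_G_animal = sigma_G_animal, sigma_G_cell = sigma_G_cell,
         sigma_P = sigma_P, sigma_gamma = sigma_gamma,
         sigma_meas = sigma_meas,
         setpoints = setpoints, background = background,
         experiment_type = experiment_type, channels = channels,
         dropout = dropout, seed = as.integer(seed)),
    class = "generative_params"
  )
}

#' Default ring-specific expression setpoints
#'
#' Arbitrary-unit mean intensities for two promoters across intestine rings
#' 1-4. The two promoters deliberately have opposite anterior-posterior
#' gradients so that pooling rings misaligns the two channels, reproducing
#' the artifact that pooling inflates apparent signaling noise.
#'
#' @return data.frame with columns `promoter`, `ring`, `setpoint`.
#' @export
default_setpoints <- function() {
  data.frame(
    promoter = rep(c("Phsp-16.2", "Pvit-2"), each = 4L),
    ring = rep(1:4, 2L),
    setpoint = c(1000, 850, 700, 600,   # heat-shock reporter, anterior-high
                 400, 550, 700, 900)    # yolk reporter, posterior-high
  )
}

#' @export
print.generative_params <- function(x, ...) {
  cat(sprintf("Generative parameters (%s): %d experiment(s) x %d animal(s) x %d cell(s)\n",
              x$experiment_type, x$n_experiments,
              x$n_animals_per_experiment, x$cells_per_animal))
  cat(sprintf("  sigma: G_animal %.3g, G_cell %.3g, P %.3g, gamma %.3g, meas %.3g\n",
              x$sigma_G_animal, x$sigma_G_cell, x$sigma_P, x$sigma_gamma,
              x$sigma_meas))
  cat(sprintf("  channels: %s\n",
              paste(sprintf("%s<-%s", names(x$channels), x$channels),
                    collapse = ", ")))
  cat(sprintf("  seed %d, dropout %.3g\n", x$seed, x$dropout))
  invisible(x)
}

#' Named generative scenarios
#'
#' Returns fully populated [generative_params()] for one of four scenarios:
#'
#' * `paper_like`: dominant shared capacity variation, small pathway and
#'   intrinsic components. Under the closed forms this regime has a Type I
#'   allele-vs-allele coefficient of determination above 0.9 in expectation
#'   and a capacity bin more than ten times the intrinsic bin.
#' * `yeast_like`: intrinsic allele noise scaled up three-fold, the regime
#'   reported for budding yeast where intrinsic noise is an order of
#'   magnitude higher than in nematode intestine cells.
#' * `high_signaling`: pathway activation noise inflated (sigma_P = 0.30).
#' * `null_no_variation`: every sigma zero; intensities equal setpoints.
#'
#' @param scenario scenario name.
#' @param experiment_type `"TypeII"` (default) or `"TypeI"`.
#' @param seed integer root seed.
#' @param ... further arguments passed to [generative_params()] to override
#'   scenario defaults (e.g. `n_animals_per_experiment`).
#' @return A [generative_params()] object.
#' @examples
#' p <- default_params("paper_like")
#' expected_eta2(p)
#' @export
default_params <- function(scenario, experiment_type = c("TypeII", "TypeI"),
                           seed = 1L, ...) {
  experiment_type <- match.arg(experiment_type)
  valid <- c("paper_like", "yeast_like", "high_signaling",
             "null_no_variation")
  if (!is.character(scenario) || length(scenario) != 1L ||
      !scenario %in% valid) {
    stop("unknown scenario; valid scenarios: ",
         paste(valid, collapse = ", "))
  }
  base <- list(sigma_G_animal = 0.20, sigma_G_cell = 0.30,
               sigma_P = 0.10, sigma_gamma = 0.05, sigma_meas = 0.03)
  sig <- switch(scenario,
    paper_like = base,
    yeast_like = utils::modifyList(base, list(sigma_gamma = 3 * 0.05)),
    high_signaling = utils::modifyList(base, list(sigma_P = 0.30)),
    null_no_variation = list(sigma_G_animal = 0, sigma_G_cell = 0,
                             sigma_P = 0, sigma_gamma = 0, sigma_meas = 0))
  do.call(generative_params,
          c(sig, list(experiment_type = experiment_type, seed = seed),
            list(...)))
}

#' Closed-form variance-bin expectations of the generative model
#'
#' For independent mean-one lognormal factors, the population values the
#' moment estimators converge to have exact closed forms. Writing
#' `sG2 = sigma_G_animal^2 + sigma_G_cell^2` and per-channel total log-scale
#' variance `st2 = sG2 + sigma_P^2 + sigma_gamma^2 + sigma_meas^2`:
#'
#' * per-channel squared coefficient of variation: `CV2 = exp(st2) - 1`;
#' * correlated variation of a Type II pair: `exp(sG2) - 1` (the capacity
#'   bin, `eta2_G_true`);
#' * correlated variation of a Type I pair: `exp(sG2 + sigma_P^2) - 1`
#'   (capacity and pathway combined, since a Type I pair shares its pathway
#'   draw);
#' * intrinsic bin `eta2_gamma_true = exp(st2) - exp(sG2 + sigma_P^2)`
#'   (uncorrelated variation of a Type I pair; multiplicative measurement
#'   noise is uncorrelated between channels and lands in this bin);
#' * pathway bin `eta2_P_true = exp(sG2 + sigma_P^2) - exp(sG2)` (Type II
#'   uncorrelated variation minus the intrinsic bin).
#'
#' @param params a [generative_params()] object.
#' @return list with elements `eta2_gamma_true`, `eta2_P_true`,
#'   `eta2_G_true`, `cv2_true`, `correlated_type1_true`,
#'   `correlated_type2_true`, `uncorrelated_type1_true`,
#'   `uncorrelated_type2_true`.
#' @export
expected_eta2 <- function(params) {
  stopifnot(inherits(params, "generative_params"))
  sG2 <- params$sigma_G_animal^2 + params$sigma_G_cell^2
  sP2 <- params$sigma_P^2
  st2 <- sG2 + sP2 + params$sigma_gamma^2 + params$sigma_meas^2
  cv2 <- exp(st2) - 1
  corr1 <- exp(sG2 + sP2) - 1
  corr2 <- exp(sG2) - 1
  list(
    eta2_gamma_true = exp(st2) - exp(sG2 + sP2),
    eta2_P_true = exp(sG2 + sP2) - exp(sG2),
    eta2_G_true = corr2,
    cv2_true = cv2,
    correlated_type1_true = corr1,
    correlated_type2_true = corr2,
    uncorrelated_type1_true = cv2 - corr1,
    uncorrelated_type2_true = cv2 - corr2
  )
}

# mean-one lognormal draws
rln1 <- function(n, sigma) {
  if (sigma == 0) rep(1, n) else exp(stats::rnorm(n, 0, sigma) - sigma^2 / 2)
}

#' Simulate a per-cell reporter measurement table
#'
#' Draws one row per measured cell under the multiplicative lognormal model
#' of [generative_params()]. Cells are spread evenly over intestine rings
#' 1-4 (two per ring at the default eight cells per animal). The table
#' carries the true latent factors in `true_*` columns so that estimator
#' recovery can be tested without re-derivation; set `keep_truth = FALSE`
#' for a blind fixture. Draws are seeded per (experiment, animal) counter,
#' so reducing `n_animals_per_experiment` leaves the remaining animals'
#' rows byte-identical.
#'
#' @param params a [generative_params()] object.
#' @param keep_truth keep the latent-truth columns (default `TRUE`).
#' @return data.frame with columns `experiment_id`, `animal_id`, `ring`,
#'   `cell_id`, `nucleus_count`, one intensity column per channel, and
#'   (optionally) `true_G_animal`, `true_G_cell`, plus per-channel
#'   `true_P_*`, `true_gamma_*`, `true_eps_*`.
#' @examples
#' cells <- simulate_cells(default_params("paper_like", seed = 42))
#' nrow(cells)  # 3 experiments x 10 animals x 8 cells = 240
#' @export
simulate_cells <- function(params, keep_truth = TRUE) {
  stopifnot(inherits(params, "generative_params"))
  chans <- params$channels
  proms <- unique(chans)
  n_rings <- 4L
  cpa <- params$cells_per_animal
  rings <- sort(rep_len(1:n_rings, cpa))
  cell_letters <- stats::ave(seq_along(rings), rings,
                             FUN = function(i) seq_along(i))
  cell_id <- paste0("int", rings, letters[cell_letters])

  # setpoint matrix: cell x channel
  sp <- matrix(NA_real_, cpa, length(chans),
               dimnames = list(NULL, names(chans)))
  for (ch in names(chans)) {
    key <- match(paste(chans[[ch]], rings),
                 paste(params$setpoints$promoter, params$setpoints$ring))
    if (anyNA(key))
      stop("no setpoint for promoter ", chans[[ch]], " in rings ",
           paste(unique(rings[is.na(key)]), collapse = ", "))
    sp[, ch] <- params$setpoints$setpoint[key]
  }

  out <- vector("list", params$n_experiments * params$n_animals_per_experiment)
  idx <- 0L
  for (e in seq_len(params$n_experiments)) {
    for (a in seq_len(params$n_animals_per_experiment)) {
      # counter-based per-animal seed: independent of other animals
      set.seed((as.numeric(params$seed) + 100003 * e + 1009 * a) %%
                 2147483647)
      G_animal <- rln1(1L, params$sigma_G_animal)
      G_cell <- rln1(cpa, params$sigma_G_cell)
      P <- matrix(NA_real_, cpa, length(proms),
                  dimnames = list(NULL, proms))
      for (p in proms) P[, p] <- rln1(cpa, params$sigma_P)
      gam <- eps <- matrix(NA_real_, cpa, length(chans),
                           dimnames = list(NULL, names(chans)))
      for (ch in names(chans)) gam[, ch] <- rln1(cpa, params$sigma_gamma)
      for (ch in names(chans)) eps[, ch] <- rln1(cpa, params$sigma_meas)
      keep <- if (params$dropout > 0) {
        stats::runif(cpa) >= params$dropout
      } else rep(TRUE, cpa)

      df <- data.frame(
        experiment_id = sprintf("exp%d", e),
        animal_id = sprintf("exp%d_an%02d", e, a),
        ring = rings,
        cell_id = cell_id,
        nucleus_count = 2L,
        stringsAsFactors = FALSE
      )
      for (ch in names(chans)) {
        df[[ch]] <- params$background[[ch]] +
          sp[, ch] * G_animal * G_cell * P[, chans[[ch]]] *
          gam[, ch] * eps[, ch]
      }
      if (keep_truth) {
        df$true_G_animal <- G_animal
        df$true_G_cell <- G_cell
        for (ch in names(chans)) {
          df[[paste0("true_P_", ch)]] <- P[, chans[[ch]]]
          df[[paste0("true_gamma_", ch)]] <- gam[, ch]
          df[[paste0("true_eps_", ch)]] <- eps[, ch]
        }
      }
      idx <- idx + 1L
      out[[idx]] <- df[keep, , drop = FALSE]
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "channels") <- names(chans)
  res
}
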