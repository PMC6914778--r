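#' Run the simulate - decompose - compare - report pipeline
#'
#' Orchestrates a full analysis from one configuration: simulate (or read)
#' per-cell tables, decompose every declared reporter pair, feed Type I
#' intrinsic noise into the Type II pathway bins, compare bins across
#' experiment replicates, optionally run the pooling check and the timer
#' population analysis, and write CSV outputs plus a plain-text summary.
#' All randomness flows from the single root `seed`; the same configuration
#' and seed produce byte-identical outputs.
#'
#' The configuration (a list, or a YAML file readable with
#' [read_run_config()]) has fields:
#'
#' * `seed` (integer), `output_dir` (created if needed);
#' * either `scenario` (a [default_params()] scenario simulated per pair) or
#'   `cells` (path to a CSV for [read_cells()], used for every pair);
#' * `pairs`: list of `name`, `type` (`"I"`/`"II"`), `channels` (2),
#'   `promoters` (2), optional `gamma_override` (numeric) for Type II pairs
#'   whose promoters lack a Type I pair in the run;
#' * optional `min_group_size` (default 5), `gain_estimator`
#'   (`"ratio"`/`"tls"`), `by_ring` (default `TRUE`: group by experiment and
#'   ring; `FALSE` pools rings), `pooled_check` (default `FALSE`);
#' * optional `timer`: list with `modes` (subset of `production`,
#'   `turnover`, `both`), `n_animals`, `sigma`, `q`.
#'
#' @param config configuration list or path to a YAML file.
#' @return Invisibly, a list with `fits` (named `"noise_decomp"` objects),
#'   `gamma` (the intrinsic-noise lookup assembled from Type I fits),
#'   `comparisons` (per Type II pair, the [compare_bins()] report across
#'   bins), `pooling` (if requested), `timer` (readouts and contrasts),
#'   and `files` (paths written: `partitions.csv`, `tests.csv`,
#'   `scatter.csv`, `timer.csv`, `summary.txt`).
#' @examples
#' \donttest{
#' cfg <- list(seed = 7, scenario = "paper_like", output_dir = tempdir(),
#'             pairs = list(
#'               list(name = "hsp16_alleles", type = "I",
#'                    channels = c("ch_green", "ch_red"),
#'                    promoters = c("Phsp-16.2", "Phsp-16.2")),
#'               list(name = "hsp16_vit2", type = "II",
#'                    channels = c("ch_green", "ch_red"),
#'                    promoters = c("Phsp-16.2", "Pvit-2"))))
#' res <- run_pipeline(cfg)
#' coef(res$fits$hsp16_vit2)
#' }
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- read_run_config(config)
  if (!is.list(config)) stop("malformed config: expected a list or a path")
  if (is.null(config$pairs) || !length(config$pairs))
    stop("malformed config: no reporter pairs declared")
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$output_dir %||% stop("malformed config: no output_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  min_gs <- as.integer(config$min_group_size %||% 5L)
  gain_est <- config$gain_estimator %||% "ratio"
  grouping <- if (isFALSE(config$by_ring)) "experiment_id" else
    c("experiment_id", "ring")

  pairs <- lapply(config$pairs, function(p) {
    if (is.null(p$name) || is.null(p$type) || is.null(p$channels) ||
        is.null(p$promoters))
      stop("malformed config: each pair needs name, type, channels, promoters")
    list(name = p$name,
         pair = reporter_pair(unlist(p$channels), unlist(p$promoters),
                              p$type),
         gamma_override = p$gamma_override)
  })
  names(pairs) <- vapply(pairs, `[[`, character(1), "name")

  cells_shared <- NULL
  if (!is.null(config$cells)) {
    cells_shared <- read_cells(config$cells, config$read)
  } else if (is.null(config$scenario)) {
    stop("malformed config: provide either 'cells' or 'scenario'")
  }
  setpoints <- if (!is.null(config$setpoints)) {
    do.call(rbind, lapply(config$setpoints, as.data.frame))
  } else default_setpoints()

  pair_cells <- function(p, i) {
    if (!is.null(cells_shared)) return(cells_shared)
    params <- default_params(
      config$scenario,
      experiment_type = if (p$pair$type == "I") "TypeI" else "TypeII",
      seed = seed + 97L * i,
      channels = stats::setNames(p$pair$promoters, p$pair$channels),
      setpoints = setpoints)
    simulate_cells(params)
  }

  # Type I pairs first: they supply the intrinsic-noise lookup
  ord <- order(vapply(pairs, function(p) p$pair$type, character(1)))
  fits <- list()
  gamma_tab <- NULL
  for (i in ord) {
    p <- pairs[[i]]
    cells <- pair_cells(p, i)
    if (p$pair$type == "I") {
      fit <- decompose_noise(cells, p$pair, grouping = grouping,
                             min_group_size = min_gs,
                             gain_estimator = gain_est)
      gamma_tab <- rbind(gamma_tab, gamma_lookup(fit))
    } else {
      gm <- if (!is.null(p$gamma_override)) p$gamma_override else gamma_tab
      if (is.null(gm))
        stop("Type II pair '", p$name, "' needs Type I intrinsic noise: ",
             "declare a Type I pair for its promoters or set gamma_override")
      fit <- decompose_noise(cells, p$pair, gamma = gm, grouping = grouping,
                             min_group_size = min_gs,
                             gain_estimator = gain_est)
    }
    fits[[p$name]] <- fit
  }
  fits <- fits[names(pairs)]

  # bin comparisons across per-experiment replicates (Type II pairs);
  # the intrinsic-noise replicates come from the Type I fits of the pair's
  # promoters (in the Type II fit the subtracted gamma is a constant)
  typeI_reps <- list()
  for (nm in names(fits)) {
    f <- fits[[nm]]
    if (f$pair$type == "I" && !is.null(f$replicates))
      typeI_reps[[f$pair$promoters[1]]] <- f$replicates$eta2_gamma
  }
  comparisons <- list()
  for (nm in names(fits)) {
    f <- fits[[nm]]
    if (f$pair$type != "II" || is.null(f$replicates) ||
        nrow(f$replicates) < 3L) next
    gi <- typeI_reps[f$pair$promoters]
    gi <- gi[!vapply(gi, is.null, logical(1))]
    bins <- list(eta2_P = f$replicates$eta2_P,
                 eta2_G = f$replicates$eta2_G)
    if (length(gi) &&
        length(unique(lengths(gi))) == 1L &&
        lengths(gi)[1] == nrow(f$replicates)) {
      bins <- c(list(eta2_gamma = rowMeans(do.call(cbind, gi))), bins)
    }
    cmp <- tryCatch(compare_bins(bins), error = function(e) e$message)
    if (is.character(cmp)) {
      message("bin comparison skipped for '", nm, "': ", cmp)
    } else {
      comparisons[[nm]] <- cmp
    }
  }

  pooling <- NULL
  if (isTRUE(config$pooled_check)) {
    ii <- which(vapply(pairs, function(p) p$pair$type, character(1)) == "II")
    if (length(ii)) {
      p <- pairs[[ii[1]]]
      gm <- if (!is.null(p$gamma_override)) p$gamma_override else gamma_tab
      pooling <- pooled_vs_grouped(pair_cells(p, ii[1]), p$pair, gm,
                                   min_group_size = min_gs)
    }
  }

  timer <- NULL
  if (!is.null(config$timer)) {
    tc <- config$timer
    k <- timer_kinetics()
    modes <- unlist(tc$modes %||% c("production", "turnover"))
    readouts <- contrasts <- list()
    for (j in seq_along(modes)) {
      ro <- simulate_timer_population(
        k, modes[j], n_animals = as.integer(tc$n_animals %||% 500L),
        sigma = tc$sigma %||% 0.5, seed = seed + 7919L * j)
      readouts[[modes[j]]] <- ro
      contrasts[[modes[j]]] <- decile_contrast(ro, q = tc$q %||% 0.10)
    }
    timer <- list(kinetics = k, steady_state_ratio = steady_state_ratio(k),
                  readouts = readouts, contrasts = contrasts)
  }

  files <- write_pipeline_outputs(out_dir, fits, comparisons, pooling, timer)
  invisible(list(fits = fits, gamma = gamma_tab, comparisons = comparisons,
                 pooling = pooling, timer = timer, files = files))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_pipeline_outputs <- function(out_dir, fits, comparisons, pooling,
                                   timer) {
  path <- function(f) file.path(out_dir, f)
  parts <- NULL
  for (nm in names(fits)) {
    g <- fits[[nm]]$groups
    g <- cbind(pair = nm, type = fits[[nm]]$pair$type, g)
    for (col in c("eta2_gamma", "eta2_P_raw", "eta2_P", "eta2_G", "clamped"))
      if (!col %in% names(g)) g[[col]] <- NA
    parts <- rbind(parts, g[, c("pair", "type", "experiment_id",
                                intersect("ring", names(g)), "n",
                                "eta2_gamma", "eta2_P_raw", "eta2_P",
                                "eta2_G", "correlated", "uncorrelated",
                                "clamped")])
  }
  utils::write.csv(parts, path("partitions.csv"), row.names = FALSE)

  tests <- NULL
  for (nm in names(comparisons)) {
    cmp <- comparisons[[nm]]
    tests <- rbind(tests, cbind(pair = nm, method = cmp$method,
                                statistic = cmp$statistic,
                                p_value = cmp$p_value, cmp$contrasts))
  }
  if (!is.null(tests))
    utils::write.csv(tests, path("tests.csv"), row.names = FALSE)

  utils::write.csv(combined_scatter(fits), path("scatter.csv"),
                   row.names = FALSE)

  if (!is.null(timer)) {
    tdf <- NULL
    for (m in names(timer$readouts))
      tdf <- rbind(tdf, cbind(mode = m, timer$readouts[[m]]))
    utils::write.csv(tdf, path("timer.csv"), row.names = FALSE)
  }

  con <- file(path("summary.txt"), "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("Dual-reporter variance decomposition: run summary")
  for (nm in names(fits)) {
    f <- fits[[nm]]
    w("")
    w("pair %s (Type %s, %s ~ %s): %d cells, %d groups", nm, f$pair$type,
      f$pair$promoters[1], f$pair$promoters[2], f$n_cells, nrow(f$groups))
    bins <- names(f$aggregate)
    for (b in bins) {
      spread <- if (!is.null(f$replicates))
        sprintf(" (replicate sd %.4g)", stats::sd(f$replicates[[b]])) else ""
      w("  %-12s %.5g%s", b, f$aggregate[[b]], spread)
    }
    if (nrow(f$skipped))
      w("  skipped groups: %s",
        paste(f$skipped$group, collapse = ", "))
  }
  for (nm in names(comparisons)) {
    cmp <- comparisons[[nm]]
    w("")
    w("bin comparison for %s: %s, statistic %.4g, p %.4g", nm, cmp$method,
      cmp$statistic, cmp$p_value)
  }
  if (!is.null(pooling)) {
    w("")
    w("pooling check: grouped eta2_P %.5g, pooled eta2_P %.5g, inflation %.5g",
      pooling$grouped_eta2_P, pooling$pooled_eta2_P, pooling$inflation)
  }
  if (!is.null(timer)) {
    w("")
    w("timer: steady-state new/old ratio %.5g", timer$steady_state_ratio)
    for (m in names(timer$contrasts)) {
      ct <- timer$contrasts[[m]]
      w("  %s mode: top %.4g, bottom %.4g, relative difference %.2f%%",
        m, ct$ratio_top, ct$ratio_bottom, 100 * ct$relative_difference)
    }
  }
  out <- c(partitions = path("partitions.csv"), tests = path("tests.csv"),
           scatter = path("scatter.csv"), timer = path("timer.csv"),
           summary = path("summary.txt"))
  out[file.exists(out)]
}
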