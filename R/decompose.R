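#' Correlated and uncorrelated variation of a paired sample
#'
#' The dual-reporter moment estimators. For paired per-cell intensities
#' `x`, `y` (already group-mean normalized):
#'
#' \deqn{uncorrelated = \frac{\mathrm{mean}((x_i - y_i)^2)}{2\,\bar x\,\bar y}, \qquad
#'       correlated = \frac{\mathrm{mean}(x_i y_i) - \bar x\,\bar y}{\bar x\,\bar y}.}
#'
#' Uncorrelated variation (dispersion across the scatterplot diagonal) is
#' the intrinsic-noise read-out of a Type I pair; correlated variation
#' (dispersion along the diagonal) measures shared capacity/pathway
#' variation. On mean-1 normalized data the two terms add up to the average
#' squared coefficient of variation of the two channels.
#'
#' @param x,y numeric vectors of equal length (n >= 2), paired per cell.
#' @return named numeric vector `c(correlated=, uncorrelated=)`.
#' @examples
#' correlated_uncorrelated(c(1, 2, 3), c(1, 2, 3))  # uncorrelated 0
#' @export
correlated_uncorrelated <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (length(x) < 2L) stop("need at least 2 paired observations")
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite and non-missing")
  mx <- mean(x); my <- mean(y)
  if (mx <= 0 || my <= 0)
    stop("mean(x) and mean(y) must be > 0 (invalid normalization)")
  c(correlated = (mean(x * y) - mx * my) / (mx * my),
    uncorrelated = mean((x - y)^2) / (2 * mx * my))
}

tls_slope <- function(x, y) {
  sxx <- stats::var(x); syy <- stats::var(y); sxy <- stats::cov(x, y)
  if (sxy == 0) return(sqrt(syy / sxx))
  (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
}

group_key <- function(cells, grouping) {
  interaction(cells[grouping], drop = TRUE, lex.order = TRUE)
}

#' Normalize channels within cell-type groups and fit relative gains
#'
#' Cell fate (which ring a cell is in) sets a rigid ratiometric expression
#' setpoint per gene pair, so intensities must be compared within groups of
#' like cells: each channel is divided by its group mean, making the
#' normalized group means exactly 1. The pre-normalization relative gain
#' ("A value") of the pair, the ratio of group mean intensities (or,
#' optionally, a total-least-squares slope), is recorded per group. Groups
#' smaller than `min_group_size`, or with a zero channel mean, are skipped
#' and listed.
#'
#' @param cells cells data.frame.
#' @param channels the two channel columns (x, y order); default the first
#'   two of [cell_channels()].
#' @param grouping character vector of grouping columns (default
#'   `c("experiment_id", "ring")`).
#' @param min_group_size smallest usable group (default 5).
#' @param gain_estimator `"ratio"` (A = mean(y)/mean(x), default) or
#'   `"tls"` (total-least-squares slope of y on x).
#' @return list with `cells` (normalized table, skipped groups removed),
#'   `gains` (one row per group: group key columns, `n`, per-channel means,
#'   `A`), and `skipped` (group, reason).
#' @export
normalize_by_group <- function(cells, channels = cell_channels(cells)[1:2],
                               grouping = c("experiment_id", "ring"),
                               min_group_size = 5L,
                               gain_estimator = c("ratio", "tls")) {
  gain_estimator <- match.arg(gain_estimator)
  if (length(channels) != 2L || !all(channels %in% names(cells)))
    stop("'channels' must name two intensity columns present in 'cells'")
  if (!all(grouping %in% names(cells)))
    stop("grouping columns not in table: ",
         paste(setdiff(grouping, names(cells)), collapse = ", "))
  key <- group_key(cells, grouping)
  gains <- NULL
  skipped <- data.frame(group = character(), reason = character(),
                        stringsAsFactors = FALSE)
  keep <- rep(FALSE, nrow(cells))
  norm <- cells
  for (g in levels(key)) {
    i <- which(key == g)
    if (length(i) < min_group_size) {
      skipped <- rbind(skipped, data.frame(
        group = g, reason = sprintf("group size %d < %d", length(i),
                                    as.integer(min_group_size))))
      next
    }
    m <- vapply(channels, function(ch) mean(cells[[ch]][i]), numeric(1))
    if (any(m == 0)) {
      skipped <- rbind(skipped, data.frame(
        group = g, reason = "zero group mean (division undefined)"))
      next
    }
    for (ch in channels) norm[[ch]][i] <- cells[[ch]][i] / mean(cells[[ch]][i])
    A <- if (gain_estimator == "ratio") m[2] / m[1] else {
      tls_slope(cells[[channels[1]]][i], cells[[channels[2]]][i])
    }
    row <- cells[i[1], grouping, drop = FALSE]
    row$n <- length(i)
    row[[paste0("mean_", channels[1])]] <- m[1]
    row[[paste0("mean_", channels[2])]] <- m[2]
    row$A <- unname(A)
    gains <- rbind(gains, row)
    keep[i] <- TRUE
  }
  if (is.null(gains))
    stop("no group satisfies the minimum group size (",
         as.integer(min_group_size), ")")
  rownames(gains) <- NULL
  out <- norm[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "channels") <- attr(cells, "channels")
  list(cells = out, gains = gains, skipped = skipped)
}

partition_groups <- function(norm_cells, channels, grouping) {
  key <- group_key(norm_cells, grouping)
  parts <- NULL
  for (g in levels(key)) {
    i <- which(key == g)
    cu <- correlated_uncorrelated(norm_cells[[channels[1]]][i],
                                  norm_cells[[channels[2]]][i])
    row <- norm_cells[i[1], grouping, drop = FALSE]
    row$n <- length(i)
    row$correlated <- unname(cu["correlated"])
    row$uncorrelated <- unname(cu["uncorrelated"])
    parts <- rbind(parts, row)
  }
  rownames(parts) <- NULL
  parts
}

# ring-matched Type I intrinsic noise with across-ring mean fallback
match_gamma <- function(gamma, promoter, ring) {
  if (is.numeric(gamma) && is.null(dim(gamma)) && length(gamma) == 1L) {
    return(list(value = unname(gamma), source = "scalar override"))
  }
  if (!is.data.frame(gamma) ||
      !all(c("promoter", "ring", "eta2_gamma") %in% names(gamma)))
    stop("'gamma' must be a scalar or a data.frame with columns ",
         "promoter, ring, eta2_gamma (see gamma_lookup())")
  rows <- gamma[gamma$promoter == promoter, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("no Type I intrinsic-noise value for promoter '", promoter,
         "'; promoters with available Type I data: ",
         paste(unique(gamma$promoter), collapse = ", "))
  if (!is.na(ring)) {
    hit <- rows[!is.na(rows$ring) & rows$ring == ring, , drop = FALSE]
    if (nrow(hit) >= 1L)
      return(list(value = mean(hit$eta2_gamma), source = "ring-matched"))
  }
  fb <- rows$eta2_gamma[is.na(rows$ring)]
  if (!length(fb)) fb <- rows$eta2_gamma
  list(value = mean(fb), source = "across-ring mean")
}

#' Decompose cell-to-cell variation of a reporter pair into noise bins
#'
#' The central fitting function. Intensities are normalized within cell-type
#' groups ([normalize_by_group()]), the correlated/uncorrelated moments are
#' computed per group ([correlated_uncorrelated()]), and the moments are
#' attributed to variance bins according to the pair type:
#'
#' * **Type I** (two copies of the same gene): `eta2_gamma` (intrinsic
#'   noise) is the uncorrelated variation; the correlated variation is the
#'   combined capacity + pathway term (the two bins cannot be separated when
#'   both channels share one signaling system).
#' * **Type II** (two distinct genes): the pathway bin is the uncorrelated
#'   variation minus the mean intrinsic noise of the two promoters measured
#'   in Type I experiments, `eta2_P_raw = uncorrelated - (gamma_x +
#'   gamma_y)/2`, clamped at zero for summaries (`eta2_P`, with
#'   `clamped` flag; the raw value is kept); the capacity bin `eta2_G` is
#'   the correlated variation.
#'
#' The aggregate over groups is their unweighted mean; per-experiment means
#' are kept as replicate values for [compare_bins()].
#'
#' @param cells cells data.frame ([read_cells()] or [simulate_cells()]).
#' @param pair a [reporter_pair()].
#' @param gamma for Type II pairs: a Type I fit of class `"noise_decomp"`, a
#'   lookup table from [gamma_lookup()] (ring-matched values preferred,
#'   across-ring mean as fallback), or a single number. Ignored for Type I.
#' @param grouping grouping columns (default experiment and ring).
#' @param min_group_size,gain_estimator passed to [normalize_by_group()].
#' @return An object of class `"noise_decomp"`: a list with `groups` (per
#'   group: key columns, `n`, bins), `aggregate` (named numeric), and
#'   `replicates` (per-experiment bin values), plus `gains`, `skipped`,
#'   `normalized`, `pair`, `grouping`, `n_cells`, `gamma_source` and `call`.
#'   Methods: `print`, `summary`, `coef`, `plot`.
#' @examples
#' cells <- simulate_cells(default_params("paper_like", "TypeI", seed = 1))
#' pair <- reporter_pair(c("ch_green", "ch_red"),
#'                       c("Phsp-16.2", "Phsp-16.2"), "I")
#' fit <- decompose_noise(cells, pair)
#' coef(fit)
#' @export
decompose_noise <- function(cells, pair, gamma = NULL,
                            grouping = c("experiment_id", "ring"),
                            min_group_size = 5L,
                            gain_estimator = c("ratio", "tls")) {
  if (!is_reporter_pair(pair)) stop("'pair' must be a reporter_pair()")
  nb <- normalize_by_group(cells, pair$channels, grouping,
                           min_group_size, match.arg(gain_estimator))
  parts <- partition_groups(nb$cells, pair$channels, grouping)
  gamma_source <- NULL

  if (pair$type == "I") {
    parts$eta2_gamma <- parts$uncorrelated
    bins <- c("eta2_gamma", "correlated", "uncorrelated")
  } else {
    if (is.null(gamma))
      stop("a Type II decomposition needs 'gamma': Type I intrinsic noise ",
           "for promoters ", paste(unique(pair$promoters), collapse = " and "))
    if (inherits(gamma, "noise_decomp")) gamma <- gamma_lookup(gamma)
    ring_col <- if ("ring" %in% grouping) parts$ring else
      rep(NA_integer_, nrow(parts))
    ga <- gb <- numeric(nrow(parts))
    src <- character(nrow(parts))
    for (k in seq_len(nrow(parts))) {
      ma <- match_gamma(gamma, pair$promoters[1], ring_col[k])
      mb <- match_gamma(gamma, pair$promoters[2], ring_col[k])
      ga[k] <- ma$value; gb[k] <- mb$value
      src[k] <- paste(unique(c(ma$source, mb$source)), collapse = "+")
    }
    parts$eta2_gamma <- (ga + gb) / 2
    parts$eta2_P_raw <- parts$uncorrelated - parts$eta2_gamma
    parts$eta2_P <- pmax(parts$eta2_P_raw, 0)
    parts$clamped <- parts$eta2_P_raw < 0
    parts$eta2_G <- parts$correlated
    gamma_source <- src
    bins <- c("eta2_gamma", "eta2_P_raw", "eta2_P", "eta2_G",
              "correlated", "uncorrelated")
  }

  aggregate <- vapply(bins, function(b) mean(parts[[b]]), numeric(1))
  replicates <- NULL
  if ("experiment_id" %in% grouping) {
    for (e in unique(parts$experiment_id)) {
      sub <- parts[parts$experiment_id == e, , drop = FALSE]
      row <- data.frame(experiment_id = e, n_groups = nrow(sub),
                        stringsAsFactors = FALSE)
      for (b in bins) row[[b]] <- mean(sub[[b]])
      replicates <- rbind(replicates, row)
    }
    rownames(replicates) <- NULL
  }

  structure(
    list(groups = parts, aggregate = aggregate, replicates = replicates,
         gains = nb$gains, skipped = nb$skipped, normalized = nb$cells,
         pair = pair, grouping = grouping, n_cells = nrow(nb$cells),
         gamma_source = gamma_source, call = match.call()),
    class = "noise_decomp"
  )
}

#' Extract a Type I intrinsic-noise lookup table from a fit
#'
#' @param fit a Type I `"noise_decomp"` object.
#' @return data.frame with columns `promoter`, `ring`, `eta2_gamma`:
#'   one ring-matched row per fitted group plus one across-ring mean row
#'   (`ring = NA`), suitable as the `gamma` argument of a Type II
#'   [decompose_noise()].
#' @export
gamma_lookup <- function(fit) {
  stopifnot(inherits(fit, "noise_decomp"))
  if (fit$pair$type != "I")
    stop("intrinsic noise is measured by Type I fits only")
  promoter <- fit$pair$promoters[1]
  g <- fit$groups
  ring <- if ("ring" %in% names(g)) as.integer(g$ring) else
    rep(NA_integer_, nrow(g))
  by_ring <- tapply(g$eta2_gamma, ring, mean)
  out <- data.frame(promoter = promoter,
                    ring = as.integer(names(by_ring)),
                    eta2_gamma = as.numeric(by_ring),
                    stringsAsFactors = FALSE)
  rbind(out, data.frame(promoter = promoter, ring = NA_integer_,
                        eta2_gamma = mean(g$eta2_gamma)))
}

#' @export
print.noise_decomp <- function(x, digits = 4, ...) {
  cat(sprintf("Dual-reporter noise decomposition (Type %s pair)\n",
              x$pair$type))
  cat(sprintf("  channels: %s ~ %s   promoters: %s ~ %s\n",
              x$pair$channels[1], x$pair$channels[2],
              x$pair$promoters[1], x$pair$promoters[2]))
  cat(sprintf("  %d cells in %d group(s) [%s]\n", x$n_cells,
              nrow(x$groups), paste(x$grouping, collapse = " x ")))
  cat("  aggregate bins (unweighted mean over groups):\n")
  print(round(x$aggregate, digits))
  if (nrow(x$skipped))
    cat(sprintf("  %d group(s) skipped; see summary()\n", nrow(x$skipped)))
  invisible(x)
}

#' @export
summary.noise_decomp <- function(object, ...) {
  structure(list(fit = object), class = "summary.noise_decomp")
}

#' @export
print.summary.noise_decomp <- function(x, digits = 4, ...) {
  f <- x$fit
  print(f, digits = digits)
  cat("\nPer-group partitions:\n")
  print(f$groups, digits = digits)
  if (!is.null(f$replicates)) {
    cat("\nPer-experiment replicate values:\n")
    print(f$replicates, digits = digits)
  }
  cat("\nRelative gains (A values):\n")
  print(f$gains, digits = digits)
  if (nrow(f$skipped)) {
    cat("\nSkipped groups:\n")
    print(f$skipped)
  }
  if (!is.null(f$gamma_source))
    cat("\nIntrinsic-noise matching:",
        paste(unique(f$gamma_source), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.noise_decomp <- function(object, ...) {
  if (object$pair$type == "I") {
    object$aggregate[c("eta2_gamma", "correlated")]
  } else {
    object$aggregate[c("eta2_gamma", "eta2_P", "eta2_G")]
  }
}

#' Scatterplot of the normalized reporter pair
#'
#' Plots the group-mean-normalized intensities of the two channels with the
#' diagonal; dispersion along the diagonal is correlated variation
#' (capacity), dispersion across it is uncorrelated variation.
#'
#' @param x a `"noise_decomp"` object.
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.noise_decomp <- function(x, ...) {
  xs <- x$normalized[[x$pair$channels[1]]]
  ys <- x$normalized[[x$pair$channels[2]]]
  lim <- range(c(xs, ys))
  plot(xs, ys, xlim = lim, ylim = lim,
       xlab = paste(x$pair$channels[1], "(normalized)"),
       ylab = paste(x$pair$channels[2], "(normalized)"),
       main = sprintf("Type %s pair: %s vs %s", x$pair$type,
                      x$pair$promoters[1], x$pair$promoters[2]), ...)
  abline(0, 1, lty = 2)
  invisible(x)
}

#' Pathway-noise inflation from pooling cell types
#'
#' Each ring has its own ratiometric setpoint for a gene pair; pooling all
#' rings before normalization mixes these setpoints into the uncorrelated
#' moment and artificially inflates the apparent pathway noise. This check
#' computes `eta2_P` twice - grouped by ring and with all rings pooled
#' (normalized over the pooled group) - and reports both and their
#' difference.
#'
#' @param cells cells data.frame.
#' @param pair a Type II [reporter_pair()].
#' @param gamma intrinsic-noise lookup, as in [decompose_noise()].
#' @param min_group_size passed to [normalize_by_group()].
#' @return list with `grouped_eta2_P`, `pooled_eta2_P`, `inflation`
#'   (pooled - grouped) and the two fits (`grouped`, `pooled`). A single
#'   ring degenerates to equality, with a warning.
#' @export
pooled_vs_grouped <- function(cells, pair, gamma, min_group_size = 5L) {
  if (!is_reporter_pair(pair) || pair$type != "II")
    stop("the pooling check applies to Type II pairs")
  if (length(unique(cells$ring)) < 2L)
    warning("single ring present: pooled and grouped are identical")
  grouped <- decompose_noise(cells, pair, gamma,
                             grouping = c("experiment_id", "ring"),
                             min_group_size = min_group_size)
  pooled <- decompose_noise(cells, pair, gamma,
                            grouping = "experiment_id",
                            min_group_size = min_group_size)
  list(grouped_eta2_P = unname(grouped$aggregate["eta2_P"]),
       pooled_eta2_P = unname(pooled$aggregate["eta2_P"]),
       inflation = unname(pooled$aggregate["eta2_P"] -
                            grouped$aggregate["eta2_P"]),
       grouped = grouped, pooled = pooled)
}

#' Pooled normalized point set for the global Type I / Type II overlay
#'
#' Stacks the per-group mean-1 normalized (x, y) points of several fits,
#' labelled by experiment type, for the "all cells from all experiments"
#' overlay in which the Type II cloud surrounds the Type I cloud whenever
#' there is pathway noise beyond the intrinsic limit.
#'
#' @param ... `"noise_decomp"` fits (or one list of them).
#' @return data.frame with columns `x`, `y`, `type` (`"I"` or `"II"`),
#'   `pair`; one row per cell.
#' @export
combined_scatter <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && !inherits(fits[[1]], "noise_decomp"))
    fits <- fits[[1]]
  out <- NULL
  for (f in fits) {
    stopifnot(inherits(f, "noise_decomp"))
    out <- rbind(out, data.frame(
      x = f$normalized[[f$pair$channels[1]]],
      y = f$normalized[[f$pair$channels[2]]],
      type = f$pair$type,
      pair = paste(f$pair$promoters, collapse = " ~ "),
      stringsAsFactors = FALSE))
  }
  out
}
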