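#' Pearson product-moment correlation
#'
#' Convenience wrapper around [stats::cor()] with the validity checks used
#' throughout the package: at least three pairs and nonzero variance in both
#' inputs (all reported coefficients of correlation or determination are
#' Pearson correlations).
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @return the correlation coefficient, in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("degenerate input")
  stats::cor(x, y)
}

shapiro_ok <- function(v, alpha) {
  if (stats::var(v) == 0) return(FALSE)  # constant: normality undecidable
  p <- tryCatch(stats::shapiro.test(v)$p.value, error = function(e) NA_real_)
  !is.na(p) && p >= alpha
}

#' Compare variance-bin replicate values across bins
#'
#' Tests whether replicate values (typically per-experiment eta-squared
#' values) differ between bins. With two bins a two-tailed two-sample
#' t-test is used; with three or more, one-way ANOVA with post hoc Tukey HSD
#' pairwise contrasts. A Shapiro-Wilk normality pre-check (per bin, at
#' `alpha`) switches to the rank-based alternatives (Mann-Whitney /
#' Kruskal-Wallis with pairwise Mann-Whitney contrasts); the choice is
#' recorded in the report.
#'
#' @param bins named list of numeric replicate vectors, >= 2 bins with >= 3
#'   values each.
#' @param alpha significance level for both the normality pre-check and the
#'   contrasts (default 0.05).
#' @return object of class `"bin_comparison"`: list with `method`,
#'   `normal` (logical per bin), `statistic`, `p_value`, `significant`, and
#'   `contrasts` (per-pair data.frame with `contrast`, `estimate`,
#'   `p_value`, `significant`; for two bins the single contrast restates the
#'   global test).
#' @examples
#' compare_bins(list(gamma = c(0.1, 0.11, 0.09), G = c(0.30, 0.31, 0.29)))
#' @export
compare_bins <- function(bins, alpha = 0.05) {
  if (!is.list(bins) || length(bins) < 2L)
    stop("'bins' must be a list of >= 2 replicate vectors")
  if (is.null(names(bins)) || any(!nzchar(names(bins))))
    names(bins) <- paste0("bin", seq_along(bins))
  n <- vapply(bins, length, integer(1))
  if (any(n < 3L)) stop("each bin needs >= 3 replicate values")
  if (all(vapply(bins, stats::var, numeric(1)) == 0))
    stop("zero variance, test undefined")
  normal <- vapply(bins, shapiro_ok, logical(1), alpha = alpha)
  values <- unlist(bins, use.names = FALSE)
  bin <- factor(rep(names(bins), n), levels = names(bins))

  if (length(bins) == 2L) {
    if (all(normal)) {
      ht <- stats::t.test(bins[[1]], bins[[2]], var.equal = TRUE)
      method <- "two-tailed two-sample t-test"
    } else {
      ht <- suppressWarnings(stats::wilcox.test(bins[[1]], bins[[2]]))
      method <- "Mann-Whitney U test"
    }
    contrasts <- data.frame(
      contrast = paste(names(bins)[2], "-", names(bins)[1]),
      estimate = mean(bins[[2]]) - mean(bins[[1]]),
      p_value = ht$p.value,
      significant = ht$p.value < alpha,
      stringsAsFactors = FALSE)
    stat <- unname(ht$statistic)
    p <- ht$p.value
  } else if (all(normal)) {
    fit <- stats::aov(values ~ bin)
    an <- summary(fit)[[1]]
    stat <- an[["F value"]][1]
    p <- an[["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit)$bin
    contrasts <- data.frame(
      contrast = rownames(tk),
      estimate = tk[, "diff"],
      p_value = tk[, "p adj"],
      significant = tk[, "p adj"] < alpha,
      stringsAsFactors = FALSE)
    rownames(contrasts) <- NULL
    method <- "one-way ANOVA with Tukey HSD"
  } else {
    ht <- stats::kruskal.test(values, bin)
    stat <- unname(ht$statistic)
    p <- ht$p.value
    combs <- utils::combn(names(bins), 2L)
    contrasts <- NULL
    for (k in seq_len(ncol(combs))) {
      a <- combs[1, k]; b <- combs[2, k]
      w <- suppressWarnings(stats::wilcox.test(bins[[b]], bins[[a]]))
      contrasts <- rbind(contrasts, data.frame(
        contrast = paste(b, "-", a),
        estimate = mean(bins[[b]]) - mean(bins[[a]]),
        p_value = w$p.value,
        significant = w$p.value < alpha,
        stringsAsFactors = FALSE))
    }
    method <- "Kruskal-Wallis with pairwise Mann-Whitney"
  }
  structure(list(method = method, normal = normal, statistic = stat,
                 p_value = p, significant = p < alpha, alpha = alpha,
                 contrasts = contrasts),
            class = "bin_comparison")
}

#' @export
print.bin_comparison <- function(x, digits = 4, ...) {
  cat(x$method, "\n")
  cat(sprintf("  statistic = %.*g, p = %.*g (%s at alpha = %g)\n",
              digits, x$statistic, digits, x$p_value,
              if (x$significant) "significant" else "not significant",
              x$alpha))
  if (!all(x$normal))
    cat("  normality pre-check failed for:",
        paste(names(x$normal)[!x$normal], collapse = ", "), "\n")
  cat("  contrasts:\n")
  print(x$contrasts, digits = digits)
  invisible(x)
}
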