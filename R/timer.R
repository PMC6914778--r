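#' Kinetic parameters of a green-to-red fluorescent timer protein
#'
#' A timer protein is translated in a green fluorescent state and matures
#' irreversibly to a red state with first-order rate `k_m` (default half-time
#' 48 h, i.e. `log(2)/48` per hour); both forms are degraded/diluted with a
#' common first-order rate `d`. Because the new/old (green/red) signal ratio
#' at steady state is `d/k_m`, independent of the production rate `s`, the
#' ratio distinguishes animals that accumulate more protein by producing
#' more (ratio unchanged) from animals that accumulate more by degrading
#' less (brighter animals shifted toward old protein).
#'
#' @param s production rate (molecules per unit time, arbitrary; >= 0).
#' @param k_m green-to-red maturation rate (per hour; >= 0, with 0 meaning
#'   no red form ever appears).
#' @param d degradation/dilution rate (per hour; >= 0).
#' @return object of class `"timer_kinetics"`.
#' @export
timer_kinetics <- function(s = 1, k_m = log(2) / 48, d = log(2) / 24) {
  if (!is.finite(s) || s < 0) stop("'s' must be >= 0")
  if (!is.finite(k_m) || k_m < 0) stop("'k_m' must be >= 0")
  if (!is.finite(d) || d < 0) stop("'d' must be >= 0")
  structure(list(s = s, k_m = k_m, d = d), class = "timer_kinetics")
}

#' @export
print.timer_kinetics <- function(x, ...) {
  cat(sprintf("Timer kinetics: s = %g, k_m = %g /h (half-time %.3g h), d = %g /h\n",
              x$s, x$k_m, if (x$k_m > 0) log(2) / x$k_m else Inf, x$d))
  invisible(x)
}

# (1 - exp(-a t)) / a, continuous at a = 0 where it equals t
frac1m <- function(a, t) if (a == 0) t else -expm1(-a * t) / a

#' Exact solution of the timer kinetics
#'
#' Solves `dG/dt = s - (k_m + d) G`, `dR/dt = k_m G - d R` from
#' `G(0) = R(0) = 0`:
#'
#' \deqn{G(t) = \frac{s}{k_m+d}\left(1 - e^{-(k_m+d)t}\right), \qquad
#'   R(t) = \frac{k_m s}{k_m+d}\left[\frac{1-e^{-dt}}{d}
#'     - e^{-dt}\,\frac{1-e^{-k_m t}}{k_m}\right],}
#'
#' with the obvious continuous limits at `d = 0` or `k_m = 0`.
#'
#' @param k a [timer_kinetics()] object.
#' @param t time(s) >= 0 (same unit as the rates).
#' @return data.frame with columns `t`, `green`, `red`.
#' @export
timer_solution <- function(k, t) {
  stopifnot(inherits(k, "timer_kinetics"))
  if (any(!is.finite(t)) || any(t < 0)) stop("'t' must be >= 0")
  kd <- k$k_m + k$d
  green <- if (kd == 0) k$s * t else k$s * vapply(t, frac1m, numeric(1), a = kd)
  red <- if (k$k_m == 0 || kd == 0) {
    rep(0, length(t))
  } else {
    k$k_m * k$s / kd *
      (vapply(t, frac1m, numeric(1), a = k$d) -
         exp(-k$d * t) * vapply(t, frac1m, numeric(1), a = k$k_m))
  }
  data.frame(t = t, green = green, red = red)
}

#' Steady-state new/old (green/red) timer ratio
#'
#' At steady state `green = s/(k_m + d)` and `red = k_m * green / d`, so the
#' new/old ratio is `d / k_m`: it depends only on turnover relative to
#' maturation, never on the production rate.
#'
#' @param k a [timer_kinetics()] object with `d > 0` and `k_m > 0`.
#' @return the ratio `d / k_m`.
#' @export
steady_state_ratio <- function(k) {
  stopifnot(inherits(k, "timer_kinetics"))
  if (k$d == 0) stop("no steady state (red unbounded)")
  if (k$k_m == 0) stop("no red form is produced when k_m = 0")
  k$d / k$k_m
}

#' Simulate steady-state timer readouts across a population of animals
#'
#' Animals differ in production rate `s` (mode `"production"`), turnover
#' rate `d` (mode `"turnover"`), or both, by independent mean-one lognormal
#' factors of scale `sigma`; each animal is read out at steady state with
#' multiplicative per-channel measurement noise. In the production regime
#' brighter animals keep the same new/old ratio; in the turnover regime
#' brighter animals (lower `d`) carry relatively more old protein and hence
#' a lower new/old ratio.
#'
#' @param k baseline [timer_kinetics()] (needs `d > 0`, `k_m > 0`).
#' @param mode `"production"`, `"turnover"`, or `"both"`.
#' @param n_animals number of animals (>= 1).
#' @param sigma lognormal scale of the varying rate(s).
#' @param sigma_meas lognormal scale of per-channel measurement noise
#'   (default 0.05).
#' @param seed integer seed; identical seed gives an identical table.
#' @return data.frame with columns `animal_id`, `green`, `red`, `total`,
#'   `ratio_new_old` (NA where `red` is 0).
#' @export
simulate_timer_population <- function(k, mode = c("production", "turnover",
                                                  "both"),
                                      n_animals = 500L, sigma = 0.5,
                                      sigma_meas = 0.05, seed = 1L) {
  stopifnot(inherits(k, "timer_kinetics"))
  mode <- match.arg(mode)
  if (k$d == 0 || k$k_m == 0)
    stop("steady-state simulation needs d > 0 and k_m > 0")
  if (n_animals < 1L) stop("'n_animals' must be >= 1")
  if (sigma < 0 || sigma_meas < 0) stop("sigma values must be >= 0")
  set.seed(as.integer(seed))
  s_i <- k$s * (if (mode %in% c("production", "both"))
    rln1(n_animals, sigma) else rep(1, n_animals))
  d_i <- k$d * (if (mode %in% c("turnover", "both"))
    rln1(n_animals, sigma) else rep(1, n_animals))
  green0 <- s_i / (k$k_m + d_i)
  red0 <- k$k_m * green0 / d_i
  green <- green0 * rln1(n_animals, sigma_meas)
  red <- red0 * rln1(n_animals, sigma_meas)
  data.frame(animal_id = sprintf("an%04d", seq_len(n_animals)),
             green = green, red = red, total = green + red,
             ratio_new_old = ifelse(red > 0, green / red, NA_real_),
             stringsAsFactors = FALSE)
}

#' New/old ratio contrast between the brightest and dimmest animals
#'
#' Ranks animals by a chosen channel and compares the mean new/old (green/
#' red) timer ratio in the top and bottom fraction `q`. An equal ratio in
#' both tails is the signature of production-driven brightness differences;
#' a lower ratio in the top tail indicates turnover-driven differences. A
#' Pearson correlation between green and red across all animals summarizes
#' the linearity of the green-red relationship.
#'
#' @param readouts data.frame from [simulate_timer_population()] (or any
#'   table with columns `green`, `red`; `total` is derived if absent).
#' @param q tail fraction, `0 < q <= 0.5` (default 0.10).
#' @param rank_channel `"total"` (default), `"green"`, or `"red"`.
#' @return object of class `"decile_contrast"`: list with `ratio_top`,
#'   `ratio_bottom`, `difference`, `relative_difference`
#'   (difference / ratio_bottom), `linearity_r`, `n_top`, `n_bottom`,
#'   `excluded` (animals with `red = 0`), `q`, `rank_channel`.
#' @export
decile_contrast <- function(readouts, q = 0.10,
                            rank_channel = c("total", "green", "red")) {
  rank_channel <- match.arg(rank_channel)
  if (!all(c("green", "red") %in% names(readouts)))
    stop("'readouts' needs columns green and red")
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q > 0.5)
    stop("'q' must be in (0, 0.5]")
  if (!"total" %in% names(readouts))
    readouts$total <- readouts$green + readouts$red
  bad <- readouts$red <= 0
  excluded <- if (any(bad) && "animal_id" %in% names(readouts))
    readouts$animal_id[bad] else character(sum(bad))
  readouts <- readouts[!bad, , drop = FALSE]
  n <- nrow(readouts)
  if (n < ceiling(1 / q))
    stop("need at least ceiling(1/q) animals with red > 0")
  k <- max(1L, as.integer(floor(q * n)))
  ord <- order(readouts[[rank_channel]])
  ratio <- readouts$green / readouts$red
  bottom <- ord[seq_len(k)]
  top <- ord[seq.int(n - k + 1L, n)]
  rb <- mean(ratio[bottom]); rt <- mean(ratio[top])
  structure(list(
    ratio_top = rt, ratio_bottom = rb, difference = rt - rb,
    relative_difference = (rt - rb) / rb,
    linearity_r = if (stats::sd(readouts$green) > 0 &&
                        stats::sd(readouts$red) > 0)
      pearson_r(readouts$green, readouts$red) else NA_real_,
    n_top = k, n_bottom = k, excluded = excluded,
    q = q, rank_channel = rank_channel), class = "decile_contrast")
}

#' @export
print.decile_contrast <- function(x, digits = 4, ...) {
  cat(sprintf("Top/bottom %.0f%% new/old timer ratio (ranked by %s)\n",
              100 * x$q, x$rank_channel))
  cat(sprintf("  top: %.*g   bottom: %.*g   difference: %.*g (%.2f%%)\n",
              digits, x$ratio_top, digits, x$ratio_bottom,
              digits, x$difference, 100 * x$relative_difference))
  cat(sprintf("  green-red linearity (Pearson r): %.*g\n",
              digits, x$linearity_r))
  if (length(x$excluded))
    cat(sprintf("  excluded %d animal(s) with red = 0\n",
                length(x$excluded)))
  invisible(x)
}
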