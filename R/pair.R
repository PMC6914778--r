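#' Define a reporter pair
#'
#' A reporter pair names the two intensity channels to be compared and the
#' promoter driving each one. In a Type I pair the two channels are
#' differently colored copies of the same reporter gene (same promoter, one
#' copy on each homologous chromosome), so their uncorrelated variation is
#' pure intrinsic noise. In a Type II pair the channels are driven by two
#' distinct promoters responding to distinct signaling systems, so their
#' uncorrelated variation contains both intrinsic and pathway (signaling)
#' noise, and their correlated variation measures general protein expression
#' capacity.
#'
#' @param channels character vector of length 2: the two intensity column
#'   names, in (x, y) order.
#' @param promoters character vector of length 2: the promoter driving each
#'   channel. For Type I pairs both entries must be identical.
#' @param type `"I"` or `"II"`.
#' @return An object of class `"reporter_pair"`.
#' @examples
#' reporter_pair(c("ch_green", "ch_red"), c("Phsp-16.2", "Phsp-16.2"), "I")
#' reporter_pair(c("ch_green", "ch_red"), c("Phsp-16.2", "Pvit-2"), "II")
#' @export
reporter_pair <- function(channels, promoters, type = c("I", "II")) {
  type <- match.arg(type)
  if (!is.character(channels) || length(channels) != 2L ||
      anyNA(channels) || channels[1] == channels[2]) {
    stop("'channels' must be two distinct channel column names")
  }
  if (!is.character(promoters) || length(promoters) != 2L || anyNA(promoters)) {
    stop("'promoters' must be a character vector of length 2")
  }
  if (type == "I" && promoters[1] != promoters[2]) {
    stop("a Type I pair must have both channels driven by the same promoter")
  }
  if (type == "II" && promoters[1] == promoters[2]) {
    stop("a Type II pair must have two distinct promoters")
  }
  structure(
    list(channels = channels, promoters = promoters, type = type),
    class = "reporter_pair"
  )
}

#' @export
print.reporter_pair <- function(x, ...) {
  cat(sprintf("Type %s reporter pair\n", x$type))
  cat(sprintf("  x: %s (%s)\n", x$channels[1], x$promoters[1]))
  cat(sprintf("  y: %s (%s)\n", x$channels[2], x$promoters[2]))
  invisible(x)
}

is_reporter_pair <- function(x) inherits(x, "reporter_pair")
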