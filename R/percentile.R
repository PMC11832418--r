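#' Percentile with the linear-interpolation convention
#'
#' Single percentile convention used throughout the package: linear
#' interpolation between order statistics at position `q * (n - 1)`, so
#' `q = 0` returns the minimum and `q = 1` the maximum (the default type-7
#' quantile of [stats::quantile()]). All thermal extremes, trimming bounds
#' and site temperature percentiles go through this function.
#'
#' @param values numeric vector, non-empty; `NA` values are not allowed.
#' @param q probability (or vector of probabilities) in `[0, 1]`.
#' @return numeric vector of the same length as `q`.
#' @examples
#' percentile(1:10, 0.9) # 9.1
#' @export
percentile <- function(values, q) {
  if (length(values) == 0L) stop("percentile: empty input")
  if (anyNA(values)) stop("percentile: NA values in input")
  if (any(q < 0 | q > 1)) stop("percentile: q must be in [0, 1]")
  stats::quantile(values, probs = q, names = FALSE, type = 7)
}

#' Trim distribution tails
#'
#' Keeps values lying between the `lower_q` and `upper_q` percentiles
#' (inclusive), the standard guard against geographic occurrence errors in
#' thermal-niche estimation. The bounds come from [percentile()], so a
#' non-empty input always retains at least its median.
#'
#' @param values numeric vector of temperatures (degC).
#' @param lower_q,upper_q tail fractions, `0 <= lower_q < upper_q <= 1`.
#' @return the retained values, in input order.
#' @export
trim_tails <- function(values, lower_q = 0.05, upper_q = 0.95) {
  if (length(values) == 0L) stop("trim_tails: no data to trim")
  if (!(lower_q >= 0 && lower_q < upper_q && upper_q <= 1)) {
    stop("trim_tails: need 0 <= lower_q < upper_q <= 1")
  }
  bounds <- percentile(values, c(lower_q, upper_q))
  values[values >= bounds[1] & values <= bounds[2]]
}
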