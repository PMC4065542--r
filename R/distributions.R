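#' Beta-PERT shape parameters
#'
#' Converts a (minimum, mode, maximum) triple into the shape parameters of the
#' classical Beta-PERT distribution (shape weight lambda = 4). A Beta-PERT draw
#' is a `Beta(alpha, beta)` variate rescaled to `[low, high]`, with mean
#' `(low + 4 mode + high) / 6`. It is the standard choice for expert-elicited
#' ranges around a most-likely value, used here for prevalence, mortalities,
#' life expectancy, the missed-case mortality ratio and unit test costs.
#'
#' @param low minimum of the support.
#' @param mode most likely value, `low <= mode <= high`.
#' @param high maximum of the support; must exceed `low`.
#' @return Named numeric vector with elements `alpha` and `beta`.
#' @examples
#' pert_shape(0, 0.5, 1)          # symmetric: alpha = beta = 3
#' pert_shape(0.23, 0.30, 0.38)   # AMI prevalence range
#' @export
pert_shape <- function(low, mode, high) {
  stopifnot(is.numeric(low), is.numeric(mode), is.numeric(high))
  if (!(low < high)) {
    stop("pert_shape: 'low' must be strictly less than 'high'", call. = FALSE)
  }
  if (mode < low || mode > high) {
    stop("pert_shape: 'mode' must lie within [low, high]", call. = FALSE)
  }
  rng <- high - low
  c(alpha = 1 + 4 * (mode - low) / rng,
    beta  = 1 + 4 * (high - mode) / rng)
}

#' Method-of-moments Beta fit from a mean and 95% interval
#'
#' Fits a `Beta(alpha, beta)` distribution to a probability-scale parameter
#' reported as a point estimate with a 95% confidence interval, reading the
#' interval width as 3.92 standard deviations. Used for the diagnostic
#' accuracy parameters and the post-AMI utility, whose sources report CIs.
#'
#' The fit requires the implied variance to be feasible for a Beta
#' distribution, i.e. `var < mean * (1 - mean)`.
#'
#' @param mean point estimate in (0, 1).
#' @param lo,hi 95% interval bounds within `[0, 1]`, `lo < hi`.
#' @return Named numeric vector with elements `alpha` and `beta`.
#' @examples
#' beta_from_mean_ci(0.44, 0.32, 0.56)  # cTnT sensitivity at <= 6 h
#' @export
beta_from_mean_ci <- function(mean, lo, hi) {
  if (!(mean > 0 && mean < 1)) {
    stop("beta_from_mean_ci: 'mean' must be strictly inside (0, 1)", call. = FALSE)
  }
  if (!(lo < hi) || lo < 0 || hi > 1) {
    stop("beta_from_mean_ci: interval must satisfy 0 <= lo < hi <= 1", call. = FALSE)
  }
  sd <- (hi - lo) / 3.92
  v <- sd^2
  if (v >= mean * (1 - mean)) {
    stop("beta_from_mean_ci: interval too wide for a Beta distribution ",
         "(variance >= mean(1-mean))", call. = FALSE)
  }
  alpha <- mean * (mean * (1 - mean) / v - 1)
  beta <- alpha * (1 - mean) / mean
  c(alpha = alpha, beta = beta)
}

#' Method-of-moments Gamma fit from a mean and range
#'
#' Fits a `Gamma(shape, scale)` distribution to a cost parameter reported as a
#' point estimate with a (min, max) range, reading the range as a 95% interval
#' (width = 3.92 standard deviations). The fitted mean `shape * scale`
#' reproduces the point estimate exactly. Used for the first-year and
#' subsequent-year AMI treatment costs.
#'
#' @param mean point estimate, > 0 (euros).
#' @param lo,hi range bounds, `0 <= lo < hi`.
#' @return Named numeric vector with elements `shape` and `scale`.
#' @examples
#' gamma_from_mean_range(12446, 9334, 15557)  # first-year AMI cost
#' @export
gamma_from_mean_range <- function(mean, lo, hi) {
  if (!(mean > 0)) stop("gamma_from_mean_range: 'mean' must be > 0", call. = FALSE)
  if (!(lo < hi) || lo < 0) {
    stop("gamma_from_mean_range: range must satisfy 0 <= lo < hi", call. = FALSE)
  }
  sd <- (hi - lo) / 3.92
  c(shape = (mean / sd)^2, scale = sd^2 / mean)
}
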