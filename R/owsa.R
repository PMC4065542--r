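#' One-way deterministic sensitivity analysis
#'
#' Varies each non-fixed parameter, one at a time, to the low and high ends
#' of its printed range with all other parameters at base value, and records
#' the resulting ICER for a chosen strategy comparison. The base parameter
#' set is untouched (perturb-and-restore), and parameters with no influence
#' on the comparison produce a span of zero.
#'
#' @param params an `ami_parameters` set.
#' @param comparison length-2 character vector `c(new, reference)`; default
#'   `c("hsTnT", "cTnT")`, the headline comparison.
#' @param effect_measure `"qaly"` (default) or `"ly"`.
#' @param settings a [cea_settings()] object.
#' @return An object of class `owsa_result`: data frame with columns
#'   `parameter`, `low_value`, `high_value`, `icer_at_low`, `icer_at_high`,
#'   `span` (absolute ICER swing).
#' @examples
#' rows <- run_owsa(ami_parameters())
#' tornado_rank(rows, 5)
#' @export
run_owsa <- function(params, comparison = c("hsTnT", "cTnT"),
                     effect_measure = c("qaly", "ly"),
                     settings = cea_settings()) {
  effect_measure <- match.arg(effect_measure)
  validate_parameter_set(params)
  strategies <- ami_strategies(params)
  if (!all(comparison %in% names(strategies))) {
    stop("run_owsa: unknown strategy in comparison: ",
         paste(setdiff(comparison, names(strategies)), collapse = ", "),
         call. = FALSE)
  }
  eff_field <- if (effect_measure == "qaly") "expected_qaly" else "expected_ly"
  pair_icer <- function(ps) {
    res <- evaluate_all(ps, settings)
    a <- res[[comparison[1]]]; b <- res[[comparison[2]]]
    icer(a$expected_cost - b$expected_cost, a[[eff_field]] - b[[eff_field]])
  }
  varied <- names(params)[vapply(params, function(p) p$family != "fixed", TRUE)]
  rows <- do.call(rbind, lapply(varied, function(nm) {
    p <- params[[nm]]
    at <- function(val) {
      ps <- params
      ps[[nm]]$value <- val
      pair_icer(ps)
    }
    data.frame(parameter = nm, low_value = p$low, high_value = p$high,
               icer_at_low = at(p$low), icer_at_high = at(p$high),
               row.names = NULL)
  }))
  if (is.null(rows)) {
    rows <- data.frame(parameter = character(), low_value = numeric(),
                       high_value = numeric(), icer_at_low = numeric(),
                       icer_at_high = numeric())
  }
  rows$span <- abs(rows$icer_at_high - rows$icer_at_low)
  structure(rows, class = c("owsa_result", "data.frame"),
            comparison = comparison, effect_measure = effect_measure)
}

#' Tornado ranking of one-way sensitivity results
#'
#' Sorts rows by descending ICER span (ties broken by parameter name) and
#' keeps the top `top_n`.
#'
#' @param rows an [run_owsa()] result (or compatible data frame with a
#'   `span` column).
#' @param top_n number of rows to keep (default 10).
#' @return The ranked, truncated data frame.
#' @export
tornado_rank <- function(rows, top_n = 10L) {
  if (!nrow(rows)) stop("tornado_rank: no rows to rank", call. = FALSE)
  stopifnot(top_n >= 1)
  out <- rows[order(-rows$span, rows$parameter), , drop = FALSE]
  out <- out[seq_len(min(top_n, nrow(out))), , drop = FALSE]
  rownames(out) <- NULL
  out
}
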