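#' Structural model settings
#'
#' Collects the structural conventions of the decision tree that are not
#' Table-style numeric parameters: how stage-2 testing is applied, how
#' competing risks combine, what false positives accrue, and how missed cases
#' are costed. Defaults encode the package's reference configuration; every
#' field is a documented alternative, not a tuning dial.
#'
#' @param continuing_symptoms fraction of stage-1 negatives who undergo the
#'   repeat test at 12 h (default 1: all negatives are retested). Untested
#'   negatives with AMI are missed cases.
#' @param stage2_cumulative if `TRUE`, the 12 h accuracies are read as
#'   cumulative ("positive at least once by 12 h") and converted to
#'   conditional stage-2 accuracies `se2 = (se12 - se6)/(1 - se6)`,
#'   `sp2 = sp12/sp6`; if `FALSE` (default) they are used directly as the
#'   conditional stage-2 values.
#' @param mortality_combination `"multiplicative"` (default) combines disease
#'   and procedural mortality as independent risks,
#'   `1 - (1 - m_ami)(1 - m_proc)`; `"additive"` sums them (capped at 1).
#' @param missed_baseline which treated-AMI mortality the missed-case risk
#'   ratio multiplies: `"early"` (default) or `"delayed"`.
#' @param fp_gets_ppci if `TRUE`, false positives undergo PPCI and face
#'   procedural mortality; default `FALSE`.
#' @param fp_workup_cost additional workup cost (euros) accrued by each false
#'   positive; default 0.
#' @param missed_accrue_costs if `TRUE` (default) surviving missed AMI cases
#'   accrue the same first-year and subsequent-year AMI cost stream as treated
#'   survivors (they have the disease and are eventually treated).
#' @param deaths_accrue_first_year if `TRUE` (default) in-hospital AMI deaths
#'   accrue the first-year treatment cost (treatment was delivered).
#' @return An object of class `cea_settings`.
#' @export
cea_settings <- function(continuing_symptoms = 1.0,
                         stage2_cumulative = FALSE,
                         mortality_combination = c("multiplicative", "additive"),
                         missed_baseline = c("early", "delayed"),
                         fp_gets_ppci = FALSE,
                         fp_workup_cost = 0,
                         missed_accrue_costs = TRUE,
                         deaths_accrue_first_year = TRUE) {
  mortality_combination <- match.arg(mortality_combination)
  missed_baseline <- match.arg(missed_baseline)
  stopifnot(continuing_symptoms >= 0, continuing_symptoms <= 1,
            fp_workup_cost >= 0)
  structure(list(continuing_symptoms = continuing_symptoms,
                 stage2_cumulative = isTRUE(stage2_cumulative),
                 mortality_combination = mortality_combination,
                 missed_baseline = missed_baseline,
                 fp_gets_ppci = isTRUE(fp_gets_ppci),
                 fp_workup_cost = fp_workup_cost,
                 missed_accrue_costs = isTRUE(missed_accrue_costs),
                 deaths_accrue_first_year = isTRUE(deaths_accrue_first_year)),
            class = "cea_settings")
}

#' @export
print.cea_settings <- function(x, ...) {
  cat("Decision-tree structural settings:\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
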