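#' Diagnostic strategy specification
#'
#' A strategy is a two-stage testing protocol: a test at presentation
#' (<= 6 h from symptom onset) and, for stage-1 negatives with continuing
#' symptoms, a repeat test at <= 12 h. It is data, not code: a name, per-stage
#' test costs and per-stage sensitivity/specificity.
#'
#' @param name strategy label.
#' @param stage1_test_cost,stage2_test_cost unit test costs in euros.
#' @param se6,sp6 sensitivity and specificity of the stage-1 (<= 6 h) test.
#' @param se12,sp12 sensitivity and specificity of the stage-2 (<= 12 h) test.
#' @return An object of class `strategy_spec`.
#' @export
strategy_spec <- function(name, stage1_test_cost, stage2_test_cost,
                          se6, sp6, se12, sp12) {
  acc <- c(se6 = se6, sp6 = sp6, se12 = se12, sp12 = sp12)
  if (any(acc < 0 | acc > 1)) {
    stop("strategy '", name, "': accuracies must lie in [0, 1]", call. = FALSE)
  }
  if (stage1_test_cost < 0 || stage2_test_cost < 0) {
    stop("strategy '", name, "': negative test cost", call. = FALSE)
  }
  structure(list(name = as.character(name),
                 stage1_test_cost = stage1_test_cost,
                 stage2_test_cost = stage2_test_cost,
                 se6 = se6, sp6 = sp6, se12 = se12, sp12 = sp12),
            class = "strategy_spec")
}

#' The three modelled diagnostic strategies
#'
#' Builds the strategy roster from a parameter set, in the fixed comparison
#' order: conventional cTnT, hsTnT, and hsTnT combined with H-FABP. Both
#' stages of a strategy use the same assay, so stage costs are equal; the
#' combination strategy's stage cost is the hsTnT unit cost plus the H-FABP
#' marginal cost.
#'
#' @param params an `ami_parameters` set.
#' @return Named list of three [strategy_spec()] objects.
#' @export
ami_strategies <- function(params) {
  v <- function(nm) param_value(params, nm)
  combo_cost <- v("cost_hstnt_test") + v("cost_hfabp_marginal")
  list(
    cTnT = strategy_spec("cTnT", v("cost_ctnt_test"), v("cost_ctnt_test"),
                         v("se6_ctnt"), v("sp6_ctnt"),
                         v("se12_ctnt"), v("sp12_ctnt")),
    hsTnT = strategy_spec("hsTnT", v("cost_hstnt_test"), v("cost_hstnt_test"),
                          v("se6_hstnt"), v("sp6_hstnt"),
                          v("se12_hstnt"), v("sp12_hstnt")),
    `hsTnT+H-FABP` = strategy_spec("hsTnT+H-FABP", combo_cost, combo_cost,
                                   v("se6_combo"), v("sp6_combo"),
                                   v("se12_combo"), v("sp12_combo"))
  )
}
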