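#' @title Decision-tree engine
#' @name tree_engine
#' @description
#' The decision tree follows a chest-pain cohort through a two-stage testing
#' protocol. Bayes' rule over disease status (prevalence) and per-stage test
#' accuracy yields six terminal pathways: true positives treated early
#' (stage-1 positive, PPCI within 4 h), true positives treated late (stage-2
#' positive, PPCI after 4 h), missed AMI (both stages negative), false
#' positives at either stage, and true negatives. Each AMI pathway carries an
#' in-hospital mortality; deaths contribute zero life years, survivors a
#' fixed discounted life expectancy weighted by the post-AMI utility.
NULL

.path_labels <- c("TP_EARLY", "TP_LATE", "FN_MISSED", "FP_EARLY", "FP_LATE", "TN")

#' Joint pathway probabilities of a strategy
#'
#' Computes the joint probability of the six terminal pathways under
#' conditional independence of the two test stages given disease status.
#' With full retesting of stage-1 negatives the probabilities are
#' `p*Se6`, `p*(1-Se6)*Se12`, `p*(1-Se6)*(1-Se12)`, `(1-p)*(1-Sp6)`,
#' `(1-p)*Sp6*(1-Sp12)` and `(1-p)*Sp6*Sp12`; they always sum to one.
#' A retesting fraction below one moves the untested stage-1 negatives into
#' the missed-AMI and true-negative pathways.
#'
#' @param prevalence pre-test AMI probability, strictly inside (0, 1).
#' @param strategy a [strategy_spec()].
#' @param settings a [cea_settings()] object.
#' @return Data frame with columns `label`, `probability`, `n_tests`
#'   (nominal test count of the pathway), `p_second_test` (probability a
#'   patient on the pathway received the repeat test) and `is_ami`.
#' @examples
#' s <- ami_strategies(ami_parameters())$cTnT
#' path_probabilities(0.30, s)
#' @export
path_probabilities <- function(prevalence, strategy, settings = cea_settings()) {
  if (!(prevalence > 0 && prevalence < 1)) {
    stop("path_probabilities: prevalence must lie strictly inside (0, 1)",
         call. = FALSE)
  }
  stopifnot(inherits(strategy, "strategy_spec"), inherits(settings, "cea_settings"))
  p <- prevalence
  f <- settings$continuing_symptoms
  se6 <- strategy$se6; sp6 <- strategy$sp6
  if (settings$stage2_cumulative) {
    # printed 12 h values read as cumulative; convert to conditional stage-2
    se12 <- if (se6 < 1) min(1, max(0, (strategy$se12 - se6) / (1 - se6))) else 0
    sp12 <- if (sp6 > 0) min(1, strategy$sp12 / sp6) else 0
  } else {
    se12 <- strategy$se12; sp12 <- strategy$sp12
  }

  pr <- c(
    TP_EARLY  = p * se6,
    TP_LATE   = p * (1 - se6) * f * se12,
    FN_MISSED = p * (1 - se6) * (1 - f * se12),
    FP_EARLY  = (1 - p) * (1 - sp6),
    FP_LATE   = (1 - p) * sp6 * f * (1 - sp12),
    TN        = (1 - p) * sp6 * (1 - f * (1 - sp12))
  )
  # probability that a patient on the path got the repeat test
  p2 <- c(
    TP_EARLY  = 0,
    TP_LATE   = 1,
    FN_MISSED = if (pr[["FN_MISSED"]] > 0) f * (1 - se12) / (1 - f * se12) else 0,
    FP_EARLY  = 0,
    FP_LATE   = 1,
    TN        = if (pr[["TN"]] > 0) f * sp12 / (1 - f * (1 - sp12)) else 0
  )
  data.frame(
    label = .path_labels,
    probability = unname(pr[.path_labels]),
    n_tests = c(1L, 2L, 2L, 1L, 2L, 2L),
    p_second_test = unname(p2[.path_labels]),
    is_ami = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    row.names = NULL
  )
}

#' Combine disease and procedural mortality
#'
#' Default is the independent-risks (multiplicative-survival) combination
#' `1 - (1 - m_ami)(1 - m_proc)`; the additive option sums the risks, capped
#' at one.
#'
#' @param m_ami in-hospital AMI mortality.
#' @param m_proc PPCI procedure-related mortality.
#' @param method `"multiplicative"` or `"additive"`.
#' @return Combined death probability.
#' @examples
#' combine_mortality(0.062, 0.0072)  # 0.0687536
#' @export
combine_mortality <- function(m_ami, m_proc,
                              method = c("multiplicative", "additive")) {
  method <- match.arg(method)
  if (any(c(m_ami, m_proc) < 0 | c(m_ami, m_proc) > 1)) {
    stop("combine_mortality: mortalities must lie in [0, 1]", call. = FALSE)
  }
  if (method == "multiplicative") 1 - (1 - m_ami) * (1 - m_proc)
  else min(1, m_ami + m_proc)
}

#' Mortality of inappropriately discharged (missed) AMI
#'
#' The risk-adjusted mortality ratio for discharged AMI patients multiplies a
#' baseline treated mortality. The default baseline is the early-PPCI
#' mortality.
#'
#' @param rr risk ratio, > 0.
#' @param baseline baseline mortality in \[0, 1\].
#' @return `rr * baseline`; errors if the product exceeds one.
#' @examples
#' missed_mortality(1.9, 0.062)  # 0.1178
#' @export
missed_mortality <- function(rr, baseline = 0.062) {
  if (rr <= 0) stop("missed_mortality: 'rr' must be positive", call. = FALSE)
  if (baseline < 0 || baseline > 1) {
    stop("missed_mortality: baseline outside [0, 1]", call. = FALSE)
  }
  m <- rr * baseline
  if (m > 1) {
    stop("missed_mortality: rr * baseline = ", format(m),
         " exceeds 1; not a probability", call. = FALSE)
  }
  m
}

# Per-pathway death probabilities and (test-cost-exclusive) accrual rules.
# Shared by the analytic tree and the patient-level microsimulation so the
# two can only diverge through the stochastic layer.
.accrual_table <- function(strategy, params, settings) {
  v <- function(nm) param_value(params, nm)
  comb <- function(a, b) combine_mortality(a, b, settings$mortality_combination)
  m_early <- comb(v("mortality_early_ppci"), v("mortality_procedural"))
  m_delayed <- comb(v("mortality_delayed_ppci"), v("mortality_procedural"))
  base <- switch(settings$missed_baseline,
                 early = v("mortality_early_ppci"),
                 delayed = v("mortality_delayed_ppci"))
  m_missed <- missed_mortality(v("mortality_ratio_missed"), base)
  m_fp <- if (settings$fp_gets_ppci) v("mortality_procedural") else 0

  le <- v("life_expectancy")
  rc <- v("discount_rate_cost")
  re <- v("discount_rate_effect")
  treat <- cost_stream(0, v("cost_ami_first_year"), v("cost_ami_subsequent_year"))
  cost_alive_treated <- discounted_lifetime_cost(treat, le, rc, FALSE)
  cost_dead <- if (settings$deaths_accrue_first_year) treat$first_year_cost else 0
  cost_alive_missed <- if (settings$missed_accrue_costs) cost_alive_treated else 0
  cost_dead_missed <- if (settings$missed_accrue_costs) cost_dead else 0
  ly_alive <- discounted_life_years(le, re)
  fp_extra <- settings$fp_workup_cost

  data.frame(
    label = .path_labels,
    death_prob = c(m_early, m_delayed, m_missed, m_fp, m_fp, 0),
    cost_alive = c(cost_alive_treated, cost_alive_treated, cost_alive_missed,
                   fp_extra, fp_extra, 0),
    cost_dead = c(cost_dead, cost_dead, cost_dead_missed, fp_extra, fp_extra, 0),
    ly_alive = c(ly_alive, ly_alive, ly_alive, 0, 0, 0),
    row.names = NULL
  )
}

#' Expected discounted outcomes of one strategy
#'
#' Evaluates the decision tree for a strategy: pathway probabilities, the
#' pathway-specific in-hospital death probabilities, and probability-weighted
#' expected discounted cost, life years and QALYs. In-hospital deaths
#' contribute zero life years; non-AMI pathways contribute zero life years
#' and QALYs by construction, so effectiveness is carried entirely by AMI
#' survival.
#'
#' @param strategy a [strategy_spec()].
#' @param params an `ami_parameters` set.
#' @param settings a [cea_settings()] object.
#' @return An object of class `strategy_result`: a list with `name`,
#'   `expected_cost`, `expected_ly`, `expected_qaly`, `ami_survival`
#'   (probability of surviving hospitalization conditional on AMI), and the
#'   annotated `paths` data frame.
#' @examples
#' p <- ami_parameters()
#' evaluate_strategy(ami_strategies(p)$hsTnT, p)
#' @export
evaluate_strategy <- function(strategy, params, settings = cea_settings()) {
  paths <- path_probabilities(param_value(params, "prevalence"), strategy, settings)
  acc <- .accrual_table(strategy, params, settings)
  stopifnot(identical(paths$label, acc$label))
  paths$death_prob <- acc$death_prob

  test_cost <- strategy$stage1_test_cost +
    paths$p_second_test * strategy$stage2_test_cost
  exp_cost_path <- test_cost +
    paths$death_prob * acc$cost_dead + (1 - paths$death_prob) * acc$cost_alive
  exp_ly_path <- (1 - paths$death_prob) * acc$ly_alive

  w <- paths$probability
  utility <- param_value(params, "utility_post_ami")
  expected_ly <- sum(w * exp_ly_path)
  ami <- paths$is_ami
  p_ami <- sum(w[ami])
  structure(list(
    name = strategy$name,
    expected_cost = sum(w * exp_cost_path),
    expected_ly = expected_ly,
    expected_qaly = qalys(expected_ly, utility),
    ami_survival = sum(w[ami] * (1 - paths$death_prob[ami])) / p_ami,
    paths = paths
  ), class = "strategy_result")
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("Strategy %-14s cost %10.2f  LY %8.5f  QALY %8.5f  AMI survival %6.4f\n",
              x$name, x$expected_cost, x$expected_ly, x$expected_qaly,
              x$ami_survival))
  invisible(x)
}

#' Evaluate all three strategies
#'
#' @param params an `ami_parameters` set.
#' @param settings a [cea_settings()] object.
#' @return Named list of `strategy_result` objects in comparison order
#'   (cTnT, hsTnT, hsTnT+H-FABP).
#' @export
evaluate_all <- function(params, settings = cea_settings()) {
  lapply(ami_strategies(params), evaluate_strategy, params = params,
         settings = settings)
}
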