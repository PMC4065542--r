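#' Patient-level microsimulation of one strategy
#'
#' Simulates `n` individual chest-pain patients through the same pathway
#' logic as the analytic tree: Bernoulli disease status at the prevalence,
#' Bernoulli stage-1 and (for retested negatives) stage-2 test results at the
#' strategy's accuracies, Bernoulli in-hospital death at the pathway-specific
#' mortality, and the shared cost/outcome accrual rules. It serves as an
#' independent Monte-Carlo oracle for [evaluate_strategy()]: by the law of
#' large numbers the cohort means converge to the tree's expectations.
#'
#' @param params an `ami_parameters` set.
#' @param strategy a [strategy_spec()] (or a strategy name).
#' @param n cohort size, >= 1.
#' @param seed integer seed.
#' @param settings a [cea_settings()] object.
#' @param keep_patients return the per-patient table (capped at
#'   `max_patient_rows` rows).
#' @param max_patient_rows cap on the retained per-patient table.
#' @return An object of class `cohort_summary`: list with `n`, `seed`,
#'   `strategy`, `means` (cost/ly/qaly), `se` (Monte-Carlo standard errors),
#'   `pathways` (frequency table over the six pathway labels) and optionally
#'   `patients`.
#' @examples
#' p <- ami_parameters()
#' simulate_cohort(p, "hsTnT", n = 5000, seed = 7)
#' @export
simulate_cohort <- function(params, strategy, n, seed = 1L,
                            settings = cea_settings(), keep_patients = FALSE,
                            max_patient_rows = 100000L) {
  if (missing(n) || n < 1) stop("simulate_cohort: 'n' must be >= 1", call. = FALSE)
  n <- as.integer(n)
  if (is.character(strategy)) strategy <- ami_strategies(params)[[strategy]]
  stopifnot(inherits(strategy, "strategy_spec"))
  validate_parameter_set(params)

  prevalence <- param_value(params, "prevalence")
  f <- settings$continuing_symptoms
  se6 <- strategy$se6; sp6 <- strategy$sp6
  if (settings$stage2_cumulative) {
    se12 <- if (se6 < 1) min(1, max(0, (strategy$se12 - se6) / (1 - se6))) else 0
    sp12 <- if (sp6 > 0) min(1, strategy$sp12 / sp6) else 0
  } else {
    se12 <- strategy$se12; sp12 <- strategy$sp12
  }
  acc <- .accrual_table(strategy, params, settings)
  utility <- param_value(params, "utility_post_ami")

  set.seed(seed)
  has_ami <- stats::runif(n) < prevalence
  p_pos1 <- ifelse(has_ami, se6, 1 - sp6)
  test1_pos <- stats::runif(n) < p_pos1
  retested <- !test1_pos & (stats::runif(n) < f)
  p_pos2 <- ifelse(has_ami, se12, 1 - sp12)
  test2_pos <- retested & (stats::runif(n) < p_pos2)

  label <- character(n)
  label[has_ami & test1_pos] <- "TP_EARLY"
  label[has_ami & test2_pos] <- "TP_LATE"
  label[has_ami & !test1_pos & !test2_pos] <- "FN_MISSED"
  label[!has_ami & test1_pos] <- "FP_EARLY"
  label[!has_ami & test2_pos] <- "FP_LATE"
  label[!has_ami & !test1_pos & !test2_pos] <- "TN"
  li <- match(label, acc$label)

  died <- stats::runif(n) < acc$death_prob[li]
  test_cost <- strategy$stage1_test_cost + retested * strategy$stage2_test_cost
  cost <- test_cost + ifelse(died, acc$cost_dead[li], acc$cost_alive[li])
  ly <- ifelse(died, 0, acc$ly_alive[li])
  qaly <- qalys(ly, utility)

  mc_se <- function(x) stats::sd(x) / sqrt(n)
  out <- list(
    n = n, seed = as.integer(seed), strategy = strategy$name,
    means = c(cost = mean(cost), ly = mean(ly), qaly = mean(qaly)),
    se = c(cost = mc_se(cost), ly = mc_se(ly), qaly = mc_se(qaly)),
    pathways = table(factor(label, levels = acc$label))
  )
  if (keep_patients) {
    k <- min(n, max_patient_rows)
    out$patients <- data.frame(
      id = seq_len(k), has_ami = has_ami[seq_len(k)],
      test1_positive = test1_pos[seq_len(k)],
      test2_positive = ifelse(retested[seq_len(k)], test2_pos[seq_len(k)], NA),
      pathway = label[seq_len(k)], died_in_hospital = died[seq_len(k)],
      discounted_cost = cost[seq_len(k)], discounted_ly = ly[seq_len(k)],
      discounted_qaly = qaly[seq_len(k)]
    )
  }
  structure(out, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Microsimulated cohort: n = %d, seed = %d, strategy = %s\n",
              x$n, x$seed, x$strategy))
  cat(sprintf("  cost %10.2f (SE %.2f)   LY %8.5f (SE %.5f)   QALY %8.5f (SE %.5f)\n",
              x$means["cost"], x$se["cost"], x$means["ly"], x$se["ly"],
              x$means["qaly"], x$se["qaly"]))
  print(x$pathways)
  invisible(x)
}

#' Validate the analytic tree against a microsimulated cohort
#'
#' Compares cohort means to the tree's expectations via Monte-Carlo z-scores
#' `(mean - expectation) / SE` for cost, life years and QALYs. The check
#' passes when every |z| is at most `z_max` (default 3). A zero standard
#' error with a non-zero discrepancy is a hard failure; small cohorts are
#' flagged as low-power.
#'
#' @param cohort a [simulate_cohort()] summary.
#' @param tree the matching [evaluate_strategy()] result.
#' @param z_max acceptance bound on |z|.
#' @return List with `table` (quantity, simulated mean, expectation, SE, z),
#'   `pass`, and `low_power`.
#' @export
compare_to_tree <- function(cohort, tree, z_max = 3) {
  stopifnot(inherits(cohort, "cohort_summary"), inherits(tree, "strategy_result"))
  if (!identical(cohort$strategy, tree$name)) {
    stop("compare_to_tree: strategy names differ (", cohort$strategy,
         " vs ", tree$name, ")", call. = FALSE)
  }
  expectation <- c(cost = tree$expected_cost, ly = tree$expected_ly,
                   qaly = tree$expected_qaly)
  diff <- cohort$means - expectation
  z <- ifelse(cohort$se > 0, diff / cohort$se,
              ifelse(diff == 0, 0, Inf))
  if (any(!is.finite(z))) {
    stop("compare_to_tree: zero Monte-Carlo SE with non-zero discrepancy",
         call. = FALSE)
  }
  list(
    table = data.frame(quantity = names(expectation),
                       simulated = unname(cohort$means),
                       expected = unname(expectation),
                       se = unname(cohort$se), z = unname(z),
                       row.names = NULL),
    pass = all(abs(z) <= z_max),
    low_power = cohort$n < 10000
  )
}
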