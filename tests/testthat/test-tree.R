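test_that("pathway probabilities follow the two-stage Bayes decomposition", {
  params <- ami_parameters()
  ct <- ami_strategies(params)$cTnT
  paths <- path_probabilities(0.30, ct)
  pr <- setNames(paths$probability, paths$label)
  expect_equal(pr[["TP_EARLY"]], 0.1320)
  expect_equal(pr[["TP_LATE"]], 0.15624)
  expect_equal(pr[["FN_MISSED"]], 0.01176)
  expect_equal(pr[["FP_EARLY"]], 0.7 * 0.08)
  expect_equal(sum(paths$probability), 1, tolerance = 1e-12)
  # perfect test: all mass on TP_EARLY and TN
  perfect <- strategy_spec("perfect", 1, 1, 1, 1, 1, 1)
  pp <- path_probabilities(0.3, perfect)
  expect_equal(setNames(pp$probability, pp$label)[c("TP_EARLY", "TN")],
               c(TP_EARLY = 0.3, TN = 0.7))
  expect_error(path_probabilities(0, ct), "prevalence")
  expect_error(path_probabilities(1.2, ct), "prevalence")
})

test_that("pathway probabilities sum to one across random draws and settings", {
  set.seed(123)
  for (i in 1:200) {
    s <- random_strategy()
    st <- cea_settings(continuing_symptoms = runif(1),
                       stage2_cumulative = runif(1) < 0.5)
    paths <- path_probabilities(runif(1, 0.01, 0.99), s, st)
    expect_lt(abs(sum(paths$probability) - 1), 1e-12)
    expect_true(all(paths$probability >= 0))
  }
})

test_that("mortality combination and missed-case mortality behave", {
  expect_equal(combine_mortality(0.062, 0.0072), 0.0687536)
  expect_equal(combine_mortality(0.37, 0), 0.37)
  expect_equal(combine_mortality(1, 0.5), 1)
  expect_equal(combine_mortality(0.1, 0.2, "additive"), 0.3)
  expect_error(combine_mortality(-0.1, 0.5), "\\[0, 1\\]")
  expect_equal(missed_mortality(1.9, 0.062), 0.1178)
  expect_equal(missed_mortality(1.0, 0.44), 0.44)
  expect_error(missed_mortality(1.9, 0.6), "exceeds 1")
})

test_that("strategy evaluation obeys the accounting limits and identities", {
  params <- ami_parameters()
  # no deaths, no discounting: LY is prevalence * life expectancy, regardless
  # of test accuracy
  zm <- zero_mortality_params(params)
  for (r in evaluate_all(zm)) {
    expect_equal(r$expected_ly, 0.30 * 8.3, tolerance = 1e-9)
    expect_equal(r$ami_survival, 1, tolerance = 1e-9)
  }
  # QALY/LY ratio equals the utility for every strategy
  for (r in evaluate_all(params)) {
    expect_equal(r$expected_qaly / r$expected_ly, 0.725, tolerance = 1e-12)
  }
  # determinism
  hs <- ami_strategies(params)$hsTnT
  expect_identical(evaluate_strategy(hs, params), evaluate_strategy(hs, params))
  # perfect-test limit: AMI survival = 1 - combined early mortality
  perfect <- strategy_spec("perfect", 1, 1, 1, 1, 1, 1)
  rp <- evaluate_strategy(perfect, params)
  expect_equal(rp$ami_survival, 1 - combine_mortality(0.062, 0.0072))
})

test_that("the high-sensitive strategy gains survival and life years", {
  res <- evaluate_all(ami_parameters())
  expect_identical(names(res), c("cTnT", "hsTnT", "hsTnT+H-FABP"))
  expect_gt(res$hsTnT$expected_ly, res$cTnT$expected_ly)
  expect_gt(res$hsTnT$ami_survival, res$cTnT$ami_survival)
  # equal accuracies and costs give pairwise identical results
  p <- ami_parameters()
  p <- set_param_values(p,
    cost_hstnt_test = 17.11, cost_hfabp_marginal = 0,
    se6_hstnt = 0.44, se12_hstnt = 0.93, sp6_hstnt = 0.92, sp12_hstnt = 0.85,
    se6_combo = 0.44, se12_combo = 0.93, sp6_combo = 0.92, sp12_combo = 0.85)
  r <- evaluate_all(p)
  expect_equal(r$hsTnT$expected_cost, r$cTnT$expected_cost)
  expect_equal(r$`hsTnT+H-FABP`$expected_ly, r$cTnT$expected_ly)
})

test_that("expected life years are monotone in sensitivity", {
  params <- ami_parameters()
  base <- ami_strategies(params)$hsTnT
  grid <- seq(0.05, 0.95, by = 0.1)
  ly_se6 <- vapply(grid, function(v) {
    s <- base; s$se6 <- v
    evaluate_strategy(s, params)$expected_ly
  }, 0)
  expect_true(all(diff(ly_se6) >= 0))
  ly_se12 <- vapply(grid, function(v) {
    s <- base; s$se12 <- v
    evaluate_strategy(s, params)$expected_ly
  }, 0)
  expect_true(all(diff(ly_se12) >= 0))
})
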