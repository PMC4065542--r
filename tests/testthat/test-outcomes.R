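test_that("discounted life years follow the year-1-undiscounted convention", {
  expect_equal(discounted_life_years(8.3, 0), 8.3)
  expect_equal(discounted_life_years(1.0, 0.04), 1.0)
  expect_equal(discounted_life_years(2.0, 0.04), 1 + 1 / 1.04)
  expect_equal(discounted_life_years(0, 0.1), 0)
  # closed-form geometric series for integer horizons
  for (le in c(3L, 5L, 10L)) {
    r <- 0.035
    expect_equal(discounted_life_years(le, r),
                 (1 - (1 + r)^-le) / (1 - (1 + r)^-1))
  }
  # monotone: non-increasing in rate, non-decreasing in horizon
  rates <- seq(0, 0.2, by = 0.02)
  v <- vapply(rates, discounted_life_years, 0, le = 8.3)
  expect_true(all(diff(v) <= 0))
  les <- seq(0.5, 12, by = 0.5)
  v <- vapply(les, discounted_life_years, 0, rate = 0.04)
  expect_true(all(diff(v) >= 0))
  expect_error(discounted_life_years(-1, 0), "non-negative")
})

test_that("lifetime cost accrual distinguishes deaths, survivors and horizons", {
  s <- cost_stream(test_cost = 10, first_year_cost = 12446,
                   subsequent_annual_cost = 2092)
  # survivor with a one-year horizon accrues no subsequent-year costs
  expect_equal(discounted_lifetime_cost(s, 1.0, 0.04), 10 + 12446)
  # two-year horizon: one subsequent year discounted one period
  s0 <- cost_stream(0, 12446, 2092)
  expect_equal(discounted_lifetime_cost(s0, 2, 0.04), 12446 + 2092 / 1.04,
               tolerance = 1e-9)
  expect_equal(round(discounted_lifetime_cost(s0, 2, 0.04), 2), 14457.54)
  # in-hospital death: test + first-year only, independent of life expectancy
  expect_equal(discounted_lifetime_cost(s, 2, 0.04, died_in_hospital = TRUE),
               discounted_lifetime_cost(s, 30, 0.04, died_in_hospital = TRUE))
  expect_equal(discounted_lifetime_cost(s, 8.3, 0.04, TRUE), 10 + 12446)
  # zero rate equals undiscounted accumulation
  expect_equal(discounted_lifetime_cost(s0, 8.3, 0), 12446 + 7.3 * 2092)
})

test_that("expected test cost reflects the repeat-testing rule", {
  params <- ami_parameters()
  strat <- ami_strategies(params)
  paths_ct <- path_probabilities(0.30, strat$cTnT)
  # P(stage-1 negative) = 0.812 for the conventional assay
  expect_equal(expected_test_cost(strat$cTnT, paths_ct), 1.812 * 17.11)
  expect_equal(round(expected_test_cost(strat$cTnT, paths_ct), 2), 31.00)
  # a stage-1 test that always returns positive is never repeated
  always_pos <- strategy_spec("pos", 17.11, 17.11, 1, 0, 1, 1)
  expect_equal(expected_test_cost(always_pos,
                                  path_probabilities(0.3, always_pos)), 17.11)
  # a perfect test is still repeated in the (healthy) stage-1 negatives
  perfect <- strategy_spec("perfect", 17.11, 17.11, 1, 1, 1, 1)
  expect_equal(expected_test_cost(perfect, path_probabilities(0.3, perfect)),
               1.7 * 17.11)
  # free stage-2 testing costs the stage-1 price
  free2 <- strategy_spec("free2", 20, 0, 0.5, 0.5, 0.5, 0.5)
  expect_equal(expected_test_cost(free2, path_probabilities(0.3, free2)), 20)
})

test_that("quality adjustment is a pure multiplication", {
  expect_equal(qalys(2.286, 0.725), 1.65735)
  expect_equal(qalys(3.7, 1), 3.7)
  expect_equal(qalys(0, 0.5), 0)
  expect_error(qalys(-1, 0.5), "negative")
  expect_error(qalys(1, 1.5), "utility")
})
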