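test_that("Beta-PERT shapes follow the classical lambda = 4 formulas", {
  expect_equal(pert_shape(0, 0.5, 1), c(alpha = 3, beta = 3))
  # AMI prevalence row: mode 0.30 on (0.23, 0.38)
  expect_equal(pert_shape(0.23, 0.30, 0.38),
               c(alpha = 1 + 4 * 0.07 / 0.15, beta = 1 + 4 * 0.08 / 0.15))
  expect_equal(unname(pert_shape(0.23, 0.30, 0.38)), c(2.8666667, 3.1333333),
               tolerance = 1e-6)
  # mode at the minimum
  expect_equal(pert_shape(0, 0, 1), c(alpha = 1, beta = 5))
  expect_error(pert_shape(1, 1, 1), "low")
  expect_error(pert_shape(0, 2, 1), "mode")
})

test_that("Beta moment fit reproduces the mean and the worked accuracy example", {
  # symmetric interval about 0.5 gives alpha = beta
  sd <- 0.1
  sh <- beta_from_mean_ci(0.5, 0.5 - 1.96 * sd, 0.5 + 1.96 * sd)
  expect_equal(sh[["alpha"]], sh[["beta"]])
  # cTnT sensitivity at <= 6 h: 0.44 (0.32, 0.56)
  sh <- beta_from_mean_ci(0.44, 0.32, 0.56)
  expect_equal(unname(sh), c(28.48298, 36.25106), tolerance = 1e-6)
  # fitted mean is exact by construction
  for (m in c(0.1, 0.44, 0.725, 0.93)) {
    s <- beta_from_mean_ci(m, max(0, m - 0.1), min(1, m + 0.1))
    expect_equal(s[["alpha"]] / (s[["alpha"]] + s[["beta"]]), m,
                 tolerance = 1e-12)
  }
  expect_error(beta_from_mean_ci(0.05, 0, 1), "too wide")
  expect_error(beta_from_mean_ci(1.2, 0, 1), "mean")
})

test_that("Gamma moment fit matches the first-year AMI cost row and its mean", {
  sh <- gamma_from_mean_range(12446, 9334, 15557)
  expect_equal(unname(sh), c(61.4656, 202.4872), tolerance = 1e-5)
  expect_equal(sh[["shape"]] * sh[["scale"]], 12446, tolerance = 1e-9)
  sh2 <- gamma_from_mean_range(2092, 1569, 2615)
  expect_equal(sh2[["shape"]] * sh2[["scale"]], 2092, tolerance = 1e-9)
  expect_error(gamma_from_mean_range(-1, 0, 1), "mean")
  expect_error(gamma_from_mean_range(5, 3, 2), "range")
})

test_that("parameter draws respect support, match the PERT mean, and are reproducible", {
  params <- ami_parameters()
  # fixed parameters are degenerate
  expect_identical(sample_parameter(params$discount_rate_cost, 10),
                   rep(0.04, 10))
  # Beta-PERT support bound: prevalence draws stay inside (0.23, 0.38)
  set.seed(42)
  d <- sample_parameter(params$prevalence, 1e5)
  expect_true(all(d >= 0.23 & d <= 0.38))
  # PERT mean identity (low + 4 mode + high) / 6, Monte-Carlo check at 3 SE
  mu <- (0.23 + 4 * 0.30 + 0.38) / 6
  expect_lt(abs(mean(d) - mu), 3 * sd(d) / sqrt(length(d)))
  # beta draws live in [0, 1]; gamma draws are positive
  set.seed(7)
  expect_true(all(sample_parameter(params$se6_ctnt, 1e4) >= 0 &
                    sample_parameter(params$se6_ctnt, 1e4) <= 1))
  expect_true(all(sample_parameter(params$cost_ami_first_year, 1e4) > 0))
  # same seed => bit-identical draws
  set.seed(99); a <- sample_parameters(params)
  set.seed(99); b <- sample_parameters(params)
  expect_identical(a, b)
})
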