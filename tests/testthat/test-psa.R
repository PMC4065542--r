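test_that("a degenerate PSA equals the base case bit-exactly", {
  fixed <- fix_all_params()
  psa <- run_psa(fixed, n_iter = 5, seed = 3)
  base <- evaluate_all(ami_parameters())
  for (s in psa$strategies) {
    expect_identical(unname(psa$cost[, s]),
                     rep(base[[s]]$expected_cost, 5))
    expect_identical(unname(psa$qaly[, s]),
                     rep(base[[s]]$expected_qaly, 5))
  }
  expect_equal(psa$n_rejected, 0L)
  # degenerate summary has zero-width intervals
  sm <- psa_summary(psa)$summary
  expect_equal(sm$cost_lo, sm$cost_hi)
})

test_that("the PSA is a pure function of its seed", {
  p <- ami_parameters()
  a <- run_psa(p, n_iter = 30, seed = 42)
  b <- run_psa(p, n_iter = 30, seed = 42)
  expect_identical(a, b)
  c <- run_psa(p, n_iter = 30, seed = 43)
  expect_false(identical(a$cost, c$cost))
  # every sampled parameter stays within its distribution's support
  expect_true(all(a$draws[, "prevalence"] >= 0.23 &
                    a$draws[, "prevalence"] <= 0.38))
  expect_true(all(a$draws[, "utility_post_ami"] >= 0 &
                    a$draws[, "utility_post_ami"] <= 1))
  expect_true(all(a$draws[, "cost_ami_first_year"] > 0))
})

test_that("PSA means are consistent with the base-case increments", {
  psa <- run_psa(ami_parameters(), n_iter = 1000, seed = 1)
  base <- evaluate_all(ami_parameters())
  dq <- psa$qaly[, "hsTnT"] - psa$qaly[, "cTnT"]
  base_dq <- base$hsTnT$expected_qaly - base$cTnT$expected_qaly
  # plug-in mean of a near-linear model: within 3 Monte-Carlo SE
  expect_lt(abs(mean(dq) - base_dq), 3 * sd(dq) / sqrt(length(dq)))
})

test_that("acceptability curves are proper probabilities with sane limits", {
  psa <- run_psa(ami_parameters(), n_iter = 200, seed = 7)
  curve <- ceac(psa, seq(0, 20000, by = 1000))
  probs <- as.matrix(curve[, psa$strategies])
  expect_true(all(probs >= 0 & probs <= 1))
  expect_equal(unname(rowSums(probs)), rep(1, nrow(curve)), tolerance = 1e-12)
  # at zero willingness to pay, the cheapest strategy wins every draw
  cheapest <- psa$strategies[apply(psa$cost, 1, which.min)]
  expect_equal(curve[curve$wtp == 0, "cTnT"], mean(cheapest == "cTnT"))
  # degenerate PSA gives a step curve with probability one on the NMB winner
  dps <- run_psa(fix_all_params(), n_iter = 3, seed = 1)
  dcurve <- ceac(dps, c(0, 1000, 20000))
  expect_equal(unname(rowSums(as.matrix(dcurve[, dps$strategies]) == 1)),
               rep(1, 3))
  expect_equal(dcurve[dcurve$wtp == 0, "cTnT"], 1)
  expect_error(ceac(psa, numeric(0)), "grid")
})

test_that("PSA summary exports the incremental cloud", {
  psa <- run_psa(ami_parameters(), n_iter = 50, seed = 5)
  out <- psa_summary(psa)
  expect_equal(nrow(out$incremental), 3 * 50)  # three ordered pairs
  expect_setequal(unique(out$incremental$comparison),
                  c("hsTnT vs cTnT", "hsTnT+H-FABP vs cTnT",
                    "hsTnT+H-FABP vs hsTnT"))
  # percentile intervals bracket the means here
  sm <- out$summary
  expect_true(all(sm$cost_lo <= sm$mean_cost & sm$mean_cost <= sm$cost_hi))
})
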