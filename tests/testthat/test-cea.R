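mk_res <- function(name, cost, eff, utility = 1) {
  structure(list(name = name, expected_cost = cost, expected_ly = eff,
                 expected_qaly = eff * utility, ami_survival = 0.9),
            class = "strategy_result")
}

test_that("ICER and NMB arithmetic", {
  expect_equal(icer(100, 0.01), 10000)
  expect_equal(icer(0, 0.5), 0)
  expect_true(is.nan(icer(5, 0)))
  expect_equal(nmb(15137.2, 1.662, 20000), 18102.8)
  expect_equal(nmb(250, 1, 0), -250)
  expect_error(nmb(1, 1, -5), "non-negative")
})

test_that("NMB ranking agrees with the ICER decision rule on random pairs", {
  set.seed(11)
  for (i in 1:500) {
    ca <- runif(1, 0, 1000); cb <- runif(1, 0, 1000)
    ea <- runif(1, 0, 5); eb <- runif(1, 0, 5)
    lambda <- runif(1, 0, 50000)
    if (ca == cb || ea == eb) next
    # orient so A is the costlier strategy
    if (ca < cb) { tmp <- ca; ca <- cb; cb <- tmp; tmp <- ea; ea <- eb; eb <- tmp }
    nmb_pref_a <- nmb(ca, ea, lambda) > nmb(cb, eb, lambda)
    if (ea > eb) {
      expect_equal(nmb_pref_a, lambda > icer(ca - cb, ea - eb))
    } else {
      # costlier and no more effective: never preferred
      expect_false(nmb_pref_a)
    }
  }
})

test_that("incremental analysis reproduces the three-way comparison layout", {
  tab <- incremental_analysis(evaluate_all(ami_parameters()), "qaly")
  expect_identical(tab$reference, "cTnT")
  expect_setequal(tab$comparisons$comparison,
                  c("hsTnT vs cTnT", "hsTnT+H-FABP vs cTnT",
                    "hsTnT+H-FABP vs hsTnT"))
  # increments are additive along the cost ordering
  cc <- tab$comparisons
  expect_equal(cc$delta_cost[cc$comparison == "hsTnT vs cTnT"] +
                 cc$delta_cost[cc$comparison == "hsTnT+H-FABP vs hsTnT"],
               cc$delta_cost[cc$comparison == "hsTnT+H-FABP vs cTnT"])
  # ICERs computed from unrounded increments
  r <- evaluate_all(ami_parameters())
  expect_equal(cc$icer_qaly[cc$comparison == "hsTnT vs cTnT"],
               (r$hsTnT$expected_cost - r$cTnT$expected_cost) /
                 (r$hsTnT$expected_qaly - r$cTnT$expected_qaly))
})

test_that("dominance flags: strong, extended, and permutation invariance", {
  # equal effects, higher cost: dominated
  tab <- incremental_analysis(list(mk_res("A", 100, 1), mk_res("B", 200, 1)))
  expect_true(tab$strategies$dominated[tab$strategies$strategy == "B"])
  expect_true(tab$comparisons$dominated[tab$comparisons$comparison == "B vs A"])

  # non-monotone ICER sequence (5 then 3): middle strategy extendedly dominated
  # brute-force frontier over the three points is A -> C
  tab <- incremental_analysis(list(mk_res("A", 0, 0), mk_res("B", 5, 1),
                                   mk_res("C", 8, 2)))
  s <- tab$strategies
  expect_true(s$ext_dominated[s$strategy == "B"])
  expect_false(s$dominated[s$strategy == "B"])
  expect_equal(s$frontier_icer[s$strategy == "C"], 4)  # (8-0)/(2-0)

  # input order never matters
  res <- evaluate_all(ami_parameters())
  tab1 <- incremental_analysis(res)
  tab2 <- incremental_analysis(rev(res))
  expect_equal(tab1$strategies, tab2$strategies)
  expect_equal(tab1$comparisons[order(tab1$comparisons$comparison), ],
               tab2$comparisons[order(tab2$comparisons$comparison), ],
               ignore_attr = TRUE)

  expect_error(incremental_analysis(list(mk_res("A", 1, 1))), "at least two")
  expect_error(incremental_analysis(list(mk_res("A", 1, 1), mk_res("A", 2, 2))),
               "duplicate")
})

test_that("CEA tables serialize with a reference-strategy row", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_cea_csv(incremental_analysis(evaluate_all(ami_parameters())), tmp)
  out <- read.csv(tmp)
  expect_identical(out$status[out$name == "cTnT"], "Reference strategy")
  expect_equal(sum(out$section == "strategy"), 3)
  expect_equal(sum(out$section == "increment"), 3)
})
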