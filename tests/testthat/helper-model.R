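# Shared fixtures for the test suite. All fixtures are built in code.

# Parameter set with every sampling distribution collapsed to its point value
# (degenerate PSA).
fix_all_params <- function(params = ami_parameters()) {
  for (nm in names(params)) params[[nm]]$family <- "fixed"
  params
}

# Parameter set with no in-hospital deaths and no discounting: expected life
# years collapse to prevalence * life expectancy by the accounting rules.
zero_mortality_params <- function(params = ami_parameters()) {
  set_param_values(params,
                   mortality_early_ppci = 0,
                   mortality_delayed_ppci = 0,
                   mortality_procedural = 0,
                   mortality_ratio_missed = 1e-9,
                   discount_rate_cost = 0,
                   discount_rate_effect = 0)
}

# Random valid accuracy/prevalence draw for property-style checks.
random_strategy <- function(name = "S") {
  strategy_spec(name,
                stage1_test_cost = runif(1, 0, 50),
                stage2_test_cost = runif(1, 0, 50),
                se6 = runif(1), sp6 = runif(1),
                se12 = runif(1), sp12 = runif(1))
}
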