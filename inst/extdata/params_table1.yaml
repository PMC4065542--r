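# Default model parameter inventory for the AMI diagnostic cost-effectiveness
# model. Costs in 2012 euros. Ranges are the published (min, max) bounds used
# by both the one-way and probabilistic sensitivity analyses; 'family' names
# the sampling distribution fitted to (value, low, high).
#
# Two entries are package corrections, documented in the methods vignette:
#   - cost_hstnt_test: EUR 21.50 micro-costed unit price (consistent with the
#     EUR 4.39 per-test increment over the conventional assay); the published
#     catalogue price of EUR 31.5 is a config alternative. Range is +/- 25%
#     of the default value, the convention used for cost parameters.
#   - cost_hfabp_marginal: NOT an externally sourced value. Placeholder for
#     the marginal cost of adding the H-FABP assay; range +/- 25%.
# Discount rates follow the Dutch pharmacoeconomic convention: 4% for costs,
# 1.5% for effects.
parameters:
  cost_ctnt_test:            {value: 17.11,  low: 12.8,    high: 21.4,    family: beta_pert, units: euros}
  cost_hstnt_test:           {value: 21.50,  low: 16.125,  high: 26.875,  family: beta_pert, units: euros}
  cost_hfabp_marginal:       {value: 10.00,  low: 7.50,    high: 12.50,   family: beta_pert, units: euros}
  cost_ami_first_year:       {value: 12446,  low: 9334,    high: 15557,   family: gamma,     units: euros}
  cost_ami_subsequent_year:  {value: 2092,   low: 1569,    high: 2615,    family: gamma,     units: euros}
  utility_post_ami:          {value: 0.725,  low: 0.544,   high: 0.906,   family: beta,      units: probability}
  discount_rate_cost:        {value: 0.04,   low: 0.04,    high: 0.04,    family: fixed,     units: rate}
  discount_rate_effect:      {value: 0.015,  low: 0.015,   high: 0.015,   family: fixed,     units: rate}
  prevalence:                {value: 0.30,   low: 0.23,    high: 0.38,    family: beta_pert, units: probability}
  mortality_ratio_missed:    {value: 1.9,    low: 1.43,    high: 2.38,    family: beta_pert, units: ratio}
  life_expectancy:           {value: 8.3,    low: 6.23,    high: 10.38,   family: beta_pert, units: years}
  mortality_early_ppci:      {value: 0.062,  low: 0.0468,  high: 0.0780,  family: beta_pert, units: probability}
  mortality_delayed_ppci:    {value: 0.103,  low: 0.077,   high: 0.1288,  family: beta_pert, units: probability}
  mortality_procedural:      {value: 0.0072, low: 0.0054,  high: 0.009,   family: beta_pert, units: probability}
  se6_ctnt:                  {value: 0.44,   low: 0.32,    high: 0.56,    family: beta,      units: probability}
  se12_ctnt:                 {value: 0.93,   low: 0.85,    high: 0.97,    family: beta,      units: probability}
  sp6_ctnt:                  {value: 0.92,   low: 0.88,    high: 0.95,    family: beta,      units: probability}
  sp12_ctnt:                 {value: 0.85,   low: 0.76,    high: 0.91,    family: beta,      units: probability}
  se6_hstnt:                 {value: 0.94,   low: 0.87,    high: 0.98,    family: beta,      units: probability}
  se12_hstnt:                {value: 0.95,   low: 0.91,    high: 0.98,    family: beta,      units: probability}
  sp6_hstnt:                 {value: 0.52,   low: 0.39,    high: 0.65,    family: beta,      units: probability}
  sp12_hstnt:                {value: 0.51,   low: 0.40,    high: 0.62,    family: beta,      units: probability}
  se6_combo:                 {value: 0.97,   low: 0.90,    high: 0.99,    family: beta,      units: probability}
  se12_combo:                {value: 0.97,   low: 0.93,    high: 0.99,    family: beta,      units: probability}
  sp6_combo:                 {value: 0.39,   low: 0.27,    high: 0.51,    family: beta,      units: probability}
  sp12_combo:                {value: 0.38,   low: 0.27,    high: 0.49,    family: beta,      units: probability}
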