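---
title: "Methods: a decision-analytic model for troponin-based AMI diagnosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a decision-analytic model for troponin-based AMI diagnosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amicea)
```

## The clinical question

Patients presenting to an emergency department with chest pain are triaged
for acute myocardial infarction (AMI) with cardiac biomarkers. Conventional
cardiac troponin T (cTnT) rises late, so a substantial share of infarctions
are biomarker-negative in the first hours after symptom onset; high-sensitive
troponin T (hsTnT) detects necrosis earlier, and heart-type fatty acid-binding
protein (H-FABP) rises earlier still. Earlier detection moves patients into
primary percutaneous coronary intervention (PPCI) sooner, and PPCI mortality
rises with delay. `amicea` quantifies whether the more expensive, more
sensitive assays buy enough earlier treatment — and hence survival, life
years and QALYs — to be worth their cost from a health-care-payer
perspective over a lifetime horizon.

## Model structure

Each strategy is a two-stage testing protocol: an assay at presentation
(≤ 6 h from symptom onset) and, for stage-1 negatives with continuing
symptoms, the same assay repeated at ≤ 12 h. Diagnosis is ruled out after
two negative tests. With prevalence $p$ and per-stage sensitivity and
specificity $(Se_6, Sp_6, Se_{12}, Sp_{12})$, Bayes' rule under conditional
independence of the stages given disease status yields six terminal
pathways:

$$
\begin{aligned}
P(\text{TP}_{early}) &= p\,Se_6, &
P(\text{TP}_{late}) &= p\,(1-Se_6)\,Se_{12}, &
P(\text{FN}) &= p\,(1-Se_6)(1-Se_{12}),\\
P(\text{FP}_{early}) &= (1-p)(1-Sp_6), &
P(\text{FP}_{late}) &= (1-p)\,Sp_6\,(1-Sp_{12}), &
P(\text{TN}) &= (1-p)\,Sp_6\,Sp_{12},
\end{aligned}
$$

which sum to one identically. Stage-1 positives receive PPCI within 4 h
(in-hospital mortality 0.062), stage-2 positives after 4 h (0.103); both are
combined with the PPCI procedural mortality 0.0072 as independent risks,
$1-(1-m)(1-m_{proc})$. Missed infarctions (two negatives) are discharged and
face the early-treatment mortality multiplied by the risk-adjusted ratio 1.9
for inappropriately discharged patients. In-hospital deaths contribute zero
life years; AMI survivors live the fixed post-AMI life expectancy of 8.3
years. Non-AMI patients contribute zero life years and QALYs — effectiveness
is carried entirely by AMI survival, so the model compares strategies by how
many infarctions they treat, how early, and how many they miss.

## Parameters and sampling distributions

The full inventory ships as `inst/extdata/params_table1.yaml` and as
`ami_parameters()`: unit test costs, AMI treatment costs (first year
€12 446, subsequent years €2 092), utility 0.725, prevalence 0.30,
mortalities, life expectancy, and the 12 accuracy values (Se/Sp at ≤ 6 h and
≤ 12 h for each strategy). Each parameter carries a (min, max) range and a
distribution family used by both sensitivity analyses:

* **Beta-PERT** for expert-elicited or range-only quantities (costs,
  prevalence, mortalities, life expectancy, the mortality ratio): classical
  $\lambda = 4$ shapes, $\alpha = 1 + 4(m-a)/(b-a)$,
  $\beta = 1 + 4(b-m)/(b-a)$, sampled as a rescaled Beta on $[a, b]$.
* **Beta** for probabilities reported with 95% confidence intervals
  (accuracies, utility): method of moments with the interval width read as
  $3.92\,\sigma$; the fitted mean reproduces the point estimate exactly.
* **Gamma** for treatment costs: method of moments with the same
  range-to-sd rule; mean preserved exactly.
* **Fixed** for the discount rates.

Ranges are the published bounds; for cost parameters they correspond to
75%–125% of the point estimate, and that convention supplies the ranges for
the two entries this package had to set itself. The hsTnT unit cost defaults
to the micro-costed €21.50 — chosen over the published catalogue €31.5
because it is the value consistent with the €4.39 per-test increment over
the €17.11 conventional assay — with the catalogue price available through
the config file. The marginal cost of adding H-FABP in the combination
strategy is nowhere sourced; it is an explicit placeholder parameter
(€10.00, flagged in the shipped YAML), and one-way results show it only
affects comparisons involving the combination arm.

The printed rates "0.4" and "0.15" for discounting are implemented as 4%
(costs) and 1.5% (effects), the Dutch pharmacoeconomic convention; both are
ordinary, configurable parameters.

## Discounting and accrual conventions

Life years and costs accrue in annual cycles with year 1 undiscounted and a
pro-rated fractional final year:
$\sum_{t=1}^{\lceil L\rceil} \min(1, L-t+1)\,(1+r)^{-(t-1)}$. There is no
half-cycle correction — the simplest defensible convention given annual
cycles and a fixed horizon, and exact in the zero-rate limit. Test costs
accrue at time zero undiscounted. In-hospital deaths accrue the first-year
treatment cost (treatment was delivered) and nothing further; survivors
accrue first-year plus discounted subsequent-year costs over the remaining
horizon. Missed-AMI survivors accrue the same treatment stream as treated
survivors on the argument that they carry the disease and are eventually
treated; a settings flag turns this off. QALYs are discounted life years
multiplied by the single post-AMI utility, so the QALY/LY ratio equals the
utility for every strategy and every draw — an exact internal identity the
test suite asserts.

## Structural choices where the design was open

`cea_settings()` gathers the conventions that are structural rather than
numeric, each with the default used throughout:

* **Retesting fraction** — all stage-1 negatives are retested
  (`continuing_symptoms = 1`), since no attrition fraction is available;
  lowering it moves untested negatives into the missed/true-negative
  pathways.
* **Stage-2 accuracy reading** — the ≤ 12 h accuracies are treated as the
  conditional accuracy of the repeat test given a stage-1 negative. The
  alternative cumulative reading ("positive at least once by 12 h") is
  implemented (`stage2_cumulative = TRUE`) and converts via
  $Se_2 = (Se_{12}-Se_6)/(1-Se_6)$, $Sp_2 = Sp_{12}/Sp_6$; under the default
  parameters the two readings differ modestly because stage-2 sensitivities
  are high.
* **False positives** — by default they accrue their test costs only: no
  PPCI, no procedural mortality, no downstream treatment cost. Flags
  (`fp_gets_ppci`, `fp_workup_cost`) expose the alternatives. The default is
  the conservative reading — no false-positive workup is priced in the
  inventory — and it matters: the hsTnT arm's specificity of 0.52 puts
  nearly half of the healthy cohort on a false-positive pathway, so any
  per-false-positive cost scales the incremental cost of the sensitive
  strategies sharply.
* **Missed-case baseline** — the 1.9 mortality ratio multiplies the
  early-PPCI mortality (its source compared discharged with hospitalized
  patients); `missed_baseline = "delayed"` is the alternative.
* **Risk combination** — disease and procedural mortality combine
  multiplicatively on survival; an additive option exists.

## Incremental analysis

Strategies are ordered by expected cost; strong dominance (costlier, no more
effective) and extended dominance (non-monotone incremental ratios along the
frontier) are flagged, with dominated strategies reported rather than
dropped. ICERs are always computed from unrounded increments. Pairwise rows
cover each new technology against the reference (lowest-cost) strategy and
each successive pair of new technologies. The net monetary benefit
$\lambda E - C$ underlies the acceptability analysis; for any pair it
reproduces the ICER decision rule, a property the suite checks on random
pairs.

## Probabilistic sensitivity analysis

`run_psa()` draws every non-fixed parameter independently per iteration
(1 000 iterations by default), shares the draw across the three strategies,
and re-evaluates the tree. Correlation between accuracy parameters of the
same assay is not modelled — a documented simplification; draws that violate
joint probability constraints (e.g. ratio × baseline mortality exceeding
one) are rejected and redrawn, with a cap of 10⁴ rejections to surface
misconfiguration. The PSA is a pure function of (parameters, iterations,
seed). Acceptability curves assign each iteration to the strategy with the
strictly highest NMB, splitting exact ties equally — ties have measure zero
under continuous draws, so the rule only matters for degenerate
configurations, where it keeps the curves summing to one. The default
willingness-to-pay grid is €0–20 000 per QALY in €500 steps.

## One-way sensitivity analysis

`run_owsa()` sets each non-fixed parameter to its printed minimum and
maximum with all others at base, recomputes the hsTnT-vs-cTnT cost-per-QALY
ratio (the headline comparison; any pair can be requested), and ranks
parameters by the absolute ICER swing for the tornado display. The
perturb-and-restore property — base-case results identical before and after
a full sweep — is asserted in the tests, as is the closed-form inverse
relation between utility and the per-QALY ratio.

## The microsimulation oracle

`simulate_cohort()` pushes individual patients through the identical pathway
logic: Bernoulli disease status, Bernoulli test results, Bernoulli
in-hospital death, then the same accrual rules. Tree and microsimulation
share one implementation of the mortality combination and of cost/outcome
accrual (an internal accrual table), so they can only diverge through
sampling noise; `compare_to_tree()` turns that into Monte-Carlo z-scores and
passes when all |z| ≤ 3. Survivor life expectancy is fixed at 8.3 years in
the microsimulation, matching the tree's expected-value use of that
parameter. This validates the tree's algebra, not the model's realism: the
generator emulates the model's own stochastic structure (independent
Bernoulli tests at the stated accuracies, homogeneous patients), not
features of real cohorts such as age- or presentation-time-dependent
accuracy, correlated serial tests, or comorbidity, so agreement says nothing
about those.

## Problem sizes and numerical choices

The default analyses are desk-scale: 1 000 PSA iterations, a 41-point
willingness-to-pay grid, 48 one-way model evaluations, and validation
cohorts of 2 × 10⁵ patients per strategy (Monte-Carlo SE on mean cost of
roughly €10, on life years of roughly 0.008). Pathway probabilities sum to
one to 10⁻¹²; moment-matched distribution means are exact to 10⁻⁹ relative;
an undefined ICER (zero effect difference) is returned as `NaN` rather than
an arbitrary large number.

## Known limitations

Effectiveness accrues only to AMI patients, so harms and costs of
false-positive workup are excluded by default even though the low
specificity of the sensitive assays makes them common; the H-FABP marginal
cost is a placeholder; accuracy parameters are sampled independently of each
other; there is no age structure, no time-continuous treatment-delay
function (only the two delay classes), and no re-presentation of missed
cases. Conclusions about the combination strategy are particularly sensitive
to the placeholder cost and to the conditional-independence reading of the
repeat test.
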