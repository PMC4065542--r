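# amicea

Decision-analytic cost-effectiveness model for biomarker-based diagnosis of
acute myocardial infarction (AMI) in chest-pain patients.

Emergency-department triage for AMI relies on cardiac biomarkers.
Conventional cardiac troponin T (cTnT) rises 8–12 h after necrosis, so early
presenters are often biomarker-negative; a high-sensitive troponin T assay
(hsTnT), alone or combined with heart-type fatty acid-binding protein
(H-FABP), detects infarction earlier at a higher unit cost. `amicea` is for
health-economic analysts who want to compare such two-stage testing
strategies: it evaluates a Bayesian sequential-testing decision tree over a
lifetime horizon from a health-care-payer perspective and reports discounted
costs, life years (LY), quality-adjusted life years (QALY) and incremental
cost-effectiveness ratios (ICERs), with probabilistic and one-way
sensitivity analysis and a patient-level microsimulation that validates the
analytic tree.

## The model in brief

Each strategy tests at presentation (≤ 6 h) and retests stage-1 negatives at
≤ 12 h. With prevalence *p* and stage accuracies (Se₆, Sp₆, Se₁₂, Sp₁₂), the
six terminal pathways have joint probabilities

    P(TP_early) = p·Se6                  P(FP_early) = (1−p)(1−Sp6)
    P(TP_late)  = p·(1−Se6)·Se12         P(FP_late)  = (1−p)·Sp6·(1−Sp12)
    P(FN)       = p·(1−Se6)(1−Se12)      P(TN)       = (1−p)·Sp6·Sp12

Stage-1 positives get PPCI within 4 h (mortality 0.062), stage-2 positives
after 4 h (0.103), each combined with procedural mortality 0.0072 as
independent risks; missed cases face 1.9 × the early-treatment mortality.
Survivors live 8.3 discounted years (effects at 1.5%/yr, costs at 4%/yr,
year 1 undiscounted) weighted by the post-AMI utility 0.725; AMI treatment
costs €12 446 in year 1 and €2 092 per later year. ICERs are Δcost/Δeffect
on unrounded increments; the acceptability analysis uses net monetary
benefit λ·E − C over λ ∈ [0, 20 000] €/QALY.

## Worked example

```r
library(amicea)
m <- cea_model()          # default parameter inventory
summary(m)
```

```
AMI diagnostic-strategy cost-effectiveness model
Strategies evaluated at base-case parameters:
Strategy cTnT           cost    7310.54  LY  2.14259  QALY  1.55338  AMI survival 0.9081
Strategy hsTnT          cost    7389.90  LY  2.19132  QALY  1.58871  AMI survival 0.9288
Strategy hsTnT+H-FABP   cost    7405.40  LY  2.19424  QALY  1.59083  AMI survival 0.9300

Incremental cost-effectiveness analysis (effect: QALY )

     strategy    cost      ly    qaly             status
         cTnT 7310.54 2.14259 1.55338 Reference strategy
        hsTnT 7389.90 2.19132 1.58871          ICER 2246
 hsTnT+H-FABP 7405.40 2.19424 1.59083          ICER 7319

Pairwise increments:
            comparison delta_cost  delta_ly delta_qaly icer_ly icer_qaly
         hsTnT vs cTnT     79.354 0.0487310  0.0353300  1628.4    2246.1
  hsTnT+H-FABP vs cTnT     94.860 0.0516535  0.0374488  1836.5    2533.1
 hsTnT+H-FABP vs hsTnT     15.506 0.0029224  0.0021188  5305.9    7318.5
```

Read: at base case the hsTnT strategy raises the probability of surviving an
AMI hospitalization from 0.908 to 0.929 by treating 94% of infarctions
within 4 h instead of 44%, gaining 0.049 discounted life years (0.035 QALYs)
per presenting patient for €79.35 extra lifetime cost — €1 628 per life year
or €2 246 per QALY, far below customary willingness-to-pay thresholds.
Adding H-FABP buys a further 0.0029 LY at €7 319/QALY, but that comparison
rests on a placeholder H-FABP unit cost (see the methods vignette).

Further verbs: `coef(m)` (parameter vector), `predict(m, params =
list(prevalence = 0.38))` (re-evaluate), `simulate(m, nsim = 1000, seed =
1)` (probabilistic sensitivity analysis), `plot(m, "ceac")` and `plot(m,
"tornado")`. Underneath sit the module functions — `ami_parameters()`,
`load_parameters()`, `path_probabilities()`, `evaluate_all()`,
`incremental_analysis()`, `run_psa()`/`ceac()`, `run_owsa()`/
`tornado_rank()`, `simulate_cohort()`/`compare_to_tree()` — and the batch
commands `cmd_basecase()`, `cmd_psa()`, `cmd_owsa()`, `cmd_simulate()`,
which write CSV artifacts plus a JSON manifest (a command-line wrapper ships
in `inst/scripts/ami_cea.R`). The parameter inventory is data:
`inst/extdata/params_table1.yaml` documents every value, range and
distribution family, and any entry can be overridden in a user config.

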