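Package: amicea
Title: Decision-Analytic Cost-Effectiveness Model for Troponin-Based
    Diagnosis of Acute Myocardial Infarction
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates a Bayesian sequential-testing decision tree
    comparing diagnostic strategies for acute myocardial infarction (AMI) in
    chest-pain patients: conventional cardiac troponin T, high-sensitive
    troponin T, and high-sensitive troponin T combined with heart-type fatty
    acid-binding protein. Computes expected discounted lifetime costs, life
    years and quality-adjusted life years per strategy, incremental
    cost-effectiveness ratios with dominance handling, probabilistic
    sensitivity analysis with Beta, Beta-PERT and Gamma parameter
    distributions, cost-effectiveness acceptability curves via the net
    monetary benefit framework, one-way (tornado) sensitivity analysis, and a
    patient-level microsimulation used as an independent oracle for the
    analytic tree.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
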