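Package: afcua
Title: Cost-Utility Microsimulation of Anticoagulation Strategies in Atrial Fibrillation
Version: 0.1.0
Authors@R:
    person("afcua", "maintainers", email = "afcua@example.org", role = c("aut", "cre"))
Description: Individual-sampling Markov microsimulation comparing standard
    warfarin dosing, pharmacogenetic-guided warfarin dosing and dabigatran
    150 mg twice daily for stroke and systemic thromboembolism prevention in
    atrial fibrillation. Simulates daily cycles over a five-year horizon with
    INR time-in-therapeutic-range categories, major bleeding and
    thromboembolic events, sequelae, treatment discontinuation, and discounted
    cost and QALY accrual. Provides incremental cost-utility analysis with
    strict and extended dominance, one-way sensitivity scenarios, probabilistic
    sensitivity analysis with beta, gamma and log-normal parameter
    distributions, cost-effectiveness acceptability curves, and a
    deterministic cohort-expectation oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
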