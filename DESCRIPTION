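Package: relapsim
Title: Patient-Level Microsimulation for the Cost-Utility of Psychological
    Treatment in Psychotic Disorders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Continuous-time patient-level state-transition (microsimulation)
    modelling of relapsing-remitting healthcare use in schizophrenia-spectrum
    disorders, and the cost-utility analysis of adding a one-time course of
    cognitive behavioural therapy for psychosis (CBTp) to treatment as usual.
    Provides a synthetic registry-like cohort generator, parametric sojourn
    sampling by cumulative-hazard inversion (exponential, Weibull, Gompertz)
    with time-limited treatment-effect hazard multipliers, common-random-number
    pairing of treatment arms, maximum-likelihood re-estimation of transition,
    episode-type and cost-equation parameters from trajectory data, discounted
    QALY and cost accumulation, incremental cost-effectiveness statistics, and
    probabilistic sensitivity analysis with cost-effectiveness acceptability
    curves, tornado tables and scenario grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    flexsurv,
    jsonlite,
    stats,
    survival,
    utils,
    yaml
Suggests:
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
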