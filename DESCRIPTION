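Package: renalcea
Title: Markov Cohort Cost-Effectiveness Model for First-Line Therapy in
    Advanced Renal-Cell Carcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-state (progression-free, progressed, dead) Markov
    cohort model comparing first-line avelumab plus axitinib against
    sunitinib in advanced renal-cell carcinoma from a US payer
    perspective.  Provides Weibull survival extrapolation of
    Kaplan-Meier curves with per-cycle transition probabilities,
    half-cycle-corrected discounted cost and QALY accumulation,
    incremental cost-effectiveness ratios with price-reduction and
    hazard-ratio subgroup scenarios, one-way (tornado) deterministic
    sensitivity analysis, and probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves.  All model inputs ship as
    an auditable YAML configuration; synthetic Kaplan-Meier cohorts and
    a synthetic life table support parameter-recovery testing without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    flexsurv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
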