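Package: isoflupk
Title: Pharmacokinetics and Detection-Time Analysis of Intramuscular
    Isoflupredone in Horses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the pharmacokinetic and pharmacodynamic analysis of a
    single 20 mg intramuscular dose of isoflupredone acetate in horses:
    a closed-form one-compartment extravascular model, non-compartmental
    analysis (terminal-slope selection and linear-up/log-down integration),
    Monte Carlo simulation of a log-normal population against the 0.1 ng/mL
    regulatory screening limit with quantile-crossing detection times, a
    two-stage population estimator with AIC-based model comparison, urinary
    fractional excretion and censored concentration summaries,
    repeated-measures baseline statistics with Bonferroni adjustment, and a
    synthetic study-data generator so every stage is testable without raw
    study data. All user-facing functions are data-frame first and return
    tibbles.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
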