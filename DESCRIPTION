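Package: nmpmito
Title: Mitochondrial Bioenergetics of Donor Livers During Normothermic Machine Perfusion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for high-resolution respirometry of liver tissue
    during normothermic machine perfusion (NMP). Converts oxygen-concentration
    traces with titration events into steady-state mass-specific fluxes per
    SUIT (substrate-uncoupler-inhibitor titration) step, derives coupling
    states (LEAK, OXPHOS, ET) and control efficiencies, computes adenylate
    energy charge, encodes perfusate-based transplantability criteria, and
    fits a multivariate linear model of a clinical early-graft-function score
    on time-integrated (AUC) mitochondrial biomarkers with stepwise-AIC term
    selection and Type II ANOVA. A synthetic-data generator with known ground
    truth stands in for the non-deposited clinical cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    dplyr,
    tidyr,
    rlang
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
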