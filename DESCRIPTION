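Package: pkbioeq
Title: Dissolution Similarity and Pharmacokinetic Bioequivalence Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for assessing in-vitro dissolution similarity and in-vivo
    relative bioavailability of multiple drug-product brands. Implements the
    model-independent difference (f1) and similarity (f2) factors with
    regulatory decision rules, noncompartmental analysis (trapezoidal AUC and
    AUMC, terminal slope selection, mean residence time and its derived
    statistics), one- and two-compartment model fitting by curve stripping
    followed by nonlinear least squares, dose-corrected relative
    bioavailability, and cross-formulation comparison by one-way ANOVA with
    Tukey's honestly-significant-difference test. A seeded study simulator
    generates dissolution curves and multi-subject oral two-compartment
    plasma studies with between-subject and residual variability and
    below-quantification censoring, so every stage of the pipeline can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
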