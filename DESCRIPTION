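Package: ionuptake
Title: Multiple Ion-Uptake Phenotyping from Depletion Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for hydroponic multiple ion-uptake phenotyping: resolves
    salt-based nutrient recipes into ionic compositions, reads ion-chromatography
    depletion exports and root-trait tables, computes net influx and specific
    uptake rates (per root length or mass), fits Michaelis-Menten kinetics to
    depletion curves via a Lambert-W closed form, assembles a standardized
    50-trait battery per plant, and estimates population-level statistics
    (variance components, broad-sense heritability, genotype-by-concentration
    ANOVA, trait correlations, PCA). Includes a seeded simulator generating
    complete synthetic experiments with known ground truth for end-to-end
    validation.
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
    lme4,
    MASS,
    car,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
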