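Package: cnahrd
Title: Homologous Recombination Deficiency Classification from Allele-Specific Copy-Number Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies somatic copy-number-alteration (CNA) features from
    allele-specific segment profiles, classifies them into an 80-component
    count vector over eight fundamental feature distributions (BP10MB, BPArm,
    CN, CNCP, OsCN, SS, NC50, BoChr), and trains a gradient-boosted classifier
    of homologous recombination deficiency (HRD) with cross-validated tree
    selection, Monte-Carlo relative-influence feature selection and a fixed
    probability cutoff. Also computes the comparator genomic-scar scores
    (LOH, TAI, LST and their sum) and ships a synthetic segment-profile
    simulator so the full pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    xgboost,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
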