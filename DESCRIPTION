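Package: eigenmet
Title: Plasma 1H-NMR Fingerprinting of Severe Burn Injury
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for 1H-NMR plasma metabolomics
    fingerprinting of severe burn injury. Simulates CPMG-like plasma
    spectra for a burn/control cohort with known ground truth, preprocesses
    spectra (baseline correction, creatinine referencing, water-region
    excision, uniform integral binning) into a samples-by-bins feature
    matrix, fits PLS-DA by NIPALS with leave-one-out cross-validation
    (PRESS, Q2, R2, SECV), selects an Eigen-metabolome of biomarker bins by
    VIP score, classifies latent scores with kernel support vector
    machines, maps selected bins to metabolites and their enzyme genes,
    and performs local hypergeometric term enrichment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    kernlab,
    mixOmics,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
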