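Package: metsel
Title: Multi-Trait Selection and Stability Analysis for Multi-Environment
    Provenance Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing multi-environment forest provenance trials:
    simulation of randomized-block common-garden experiments, REML variance
    decomposition of per-site and across-site mixed models with likelihood
    ratio tests and BLUPs, the multi-trait genotype-ideotype distance index
    (MGIDI) built on factor analysis with varimax rotation, the WAASB
    stability statistic from the singular value decomposition of the
    genotype-by-environment interaction BLUP matrix, the WAASBY
    performance/stability blend, and the multi-trait stability index (MTSI),
    together with selection at a stated intensity and selection differentials.
    Includes an end-to-end reproducible pipeline driver.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
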