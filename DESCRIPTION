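Package: poisqpcr
Title: Poisson Occupancy Statistics and Analytical Validation for
    Limiting-Dilution qPCR Assays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Statistical toolkit for the analytical validation of
    allele-specific qPCR assays run at or near single-copy input, as used
    for circulating tumor DNA (ctDNA) mutation detection. Implements
    Poisson occupancy theory for limiting-dilution wells (theoretical
    empty-well fractions, dropout-based lambda estimates with exact
    binomial confidence intervals, censored and rounded-count maximum
    likelihood estimators, proficiency checks), log-linear standard-curve
    and master-curve fitting with amplification efficiency and copy-number
    interpolation, paired delta-Ct interference analysis for wild-type DNA
    background, confusion-matrix sensitivity/specificity with
    mutant-allele-fraction limits of detection, Clopper-Pearson detection
    rates, inter/intra-assay reproducibility summaries, and a seeded
    synthetic plate-data generator so the entire pipeline is testable
    without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
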