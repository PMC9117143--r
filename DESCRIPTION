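Package: btmbtools
Title: Blood Tumor Mutational Burden Scoring and Biomarker-Stratified
    Trial Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scores blood tumor mutational burden (bTMB) from circulating
    tumor DNA variant calls over a fixed hybrid-capture panel (maximum
    somatic allele frequency estimation, germline and driver filtering,
    substitution counting, mutations-per-megabase conversion) and analyses
    biomarker-stratified single-arm trial efficacy: objective response
    rates with Blaker exact intervals, Cochran-Mantel-Haenszel tests,
    Kaplan-Meier curves with Greenwood variance and Brookmeyer-Crowley
    median intervals, log-rank tests, Cox hazard ratios with Efron tie
    handling, bTMB cutoff sweeps, inverse-probability-weighted propensity
    adjustment of ctDNA-fraction subgroups, and gene-level prevalence
    association under false-discovery-rate control. A synthetic cohort
    generator emulating a ~152-patient non-small cell lung cancer trial
    drives all analyses without access-controlled patient data.
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
    purrr,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
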