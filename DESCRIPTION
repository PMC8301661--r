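Package: mrprofile
Title: Robust Profile-Likelihood Mendelian Randomization with Pleiotropy
    Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multivariable Mendelian randomization from three-sample GWAS
    summary statistics under pervasive horizontal pleiotropy. Estimates
    causal effects and an overdispersion variance by maximizing an adjusted
    robust profile likelihood with Tukey's biweight loss, accounts for
    sample overlap between cohorts through a shared correlation matrix
    estimated from null SNPs, detects multiple pleiotropic pathways through
    multi-modality of the profile likelihood, assigns marker SNPs to modes,
    diagnoses causal direction by comparing forward and reverse profiles,
    and combines evidence across instrument-selection p-value thresholds
    with partial-conjunction replicability p-values. Includes a synthetic
    summary-statistics generator emulating the three-cohort design with
    configurable pleiotropy, pathway confounding and cohort overlap.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
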