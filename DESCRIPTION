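Package: prsexcess
Title: Polygenic Risk Score Attribution of Excess Disease Prevalence
    Between Populations
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds curated polygenic risk score (PRS) panels from
    GWAS-style effect tables (inverse-variance meta-analysis of duplicated
    variants, allele harmonisation, LD clumping), scores genotype dosage
    matrices, fits case/control association models (Gaussian identity-link
    group comparison and logistic regression on kinship-filtered unrelated
    subsets) with Nagelkerke pseudo-R2 and ROC/AUC evaluation, compares
    control PRS distributions and risk-allele frequencies between
    populations, and converts PRS-implied log odds ratios into equivalent
    excess cases per 100,000 against a baseline prevalence. Includes a
    synthetic three-cohort generator (one mainland population and two
    population isolates with an elevated-frequency large-effect HLA-like
    locus) so the full pipeline is testable without access to private
    cohort genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
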