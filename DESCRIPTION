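Package: proteovar
Title: Variance Decomposition, Heritability and Association Analysis for
    Multiplexed Protein Biomarker Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting non-disease variation in circulating
    protein biomarkers measured by multiplexed proximity extension assays
    (PEA) in family-structured population cohorts. Normalizes plate-level
    Cq measurements into ddCq values with negative-control detection
    limits and sample/protein quality control, decomposes per-protein
    variance across clinical and lifestyle covariates by sequential
    analysis of variance, estimates kinship-aware narrow-sense
    heritability under a polygenic model, runs a family-adjusted
    score-test genome-wide association scan with discovery, replication,
    combined and conditional phases, types ABO blood groups from four tag
    SNPs, and derives genotype- and covariate-stratified personalized
    reference intervals. A gene-dropping simulator generates complete
    synthetic family cohorts (pedigree, genotypes, covariates, heritable
    traits and raw plates) so the whole pipeline is testable end to end
    without access to individual-level study data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
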