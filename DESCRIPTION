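Package: strainspike
Title: Benchmarking Strain Deconvolution in Simulated Live Biotherapeutic Product Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates single-strain live biotherapeutic product (LBP) trial
    cohorts as SNV metagenotypes with a spiked-in product strain, deconvolves
    strains with a penalized binomial-mixture engine, and scores genotype
    recovery (Jaccard matching and collapsing), spike-in detection and
    abundance accuracy (RMSE by sequencing depth), strain-level alpha
    diversity (effective number of strains), and community dissimilarity
    (weighted UniFrac on genotype-distance trees). Also selects core
    biallelic SNV sites from genome panels and ingests inference tables
    produced by external strain-deconvolution tools for identical scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    phangorn
Config/testthat/edition: 3
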