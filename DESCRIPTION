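Package: methylICA
Title: Discovery and Removal of Sex Confound Factors in Genome-Wide
    Methylation Data by Independent Component Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for epigenome-wide association studies on methylation
    beta-value matrices: site-level quality-control filtering, sitewise
    two-sample t-tests and Pearson correlations with Bonferroni control,
    PCA with variance-retention component selection, Bell-Sejnowski
    infomax independent component analysis, identification of a latent
    factor associated with a single phenotype (typically sex) and with
    nothing else, and rank-one removal of that factor from the data so
    that downstream association tests are no longer confounded. Includes
    a seeded synthetic-cohort simulator with planted sex and age factors
    for validation, and an end-to-end pipeline with text-file artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
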