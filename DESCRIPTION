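Package: twinewas
Title: Methylome and Transcriptome Association Analysis for Discordant
    Monozygotic Twin Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for epigenome-wide and transcriptome-wide
    association studies in monozygotic twin pairs discordant for a
    phenotype. Implements a within-pair log2-ratio mixed model with batch
    random effects, differentially methylated region (DMR) calling from
    probe-level results, cis methylation-expression integration with a
    permutation-derived significance threshold, weighted co-methylation
    and co-expression network analysis with differential-connectivity
    testing, Fisher-exact overlap enrichment, a case-control replication
    scan, and a synthetic twin-cohort generator with ground-truth labels
    for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
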