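Package: altigrad
Title: Environmental Association of Pooled Allele Frequencies Along
    Altitudinal Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects environment-associated genetic differentiation among
    populations from pooled sequencing (pool-seq) allele counts. Implements
    sub-sampled allele-frequency estimation, per-SNP and gene-level pool FST
    with Fisher's exact significance, population-specific SNP classification,
    neighbour-joining and bootstrap majority-rule consensus trees from FST
    distance matrices, partial Mantel tests of gene-level FST against
    bio-climatic distance matrices with simulation-derived effect-size
    thresholds and a three-step stringency filter, and GO term
    over-representation with Benjamini-Yekutieli FDR control. Ships a
    synthetic-data generator with planted truth (Balding-Nichols drift,
    logistic frequency-environment links, overdispersed coverage) so the
    whole inference chain is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    graphics,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
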