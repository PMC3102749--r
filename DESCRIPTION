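Package: tyGCR
Title: Ty1 Repeat-Mediated Gross Chromosomal Rearrangement Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying gross chromosomal rearrangements (GCRs)
    mediated by high copy number Ty1/Ty2 retrotransposon repeats in
    Saccharomyces cerevisiae. Implements Luria-Delbruck fluctuation-assay
    rate estimation with the Lea-Coulson median estimator and exact
    order-statistic confidence intervals, array-CGH copy-number
    segmentation with boundaries anchored to annotated repeat elements,
    a Class I-V taxonomy of Ty-mediated rearrangements with mechanism
    inference (de novo telomere addition, monocentric homologous
    recombination, dicentric breakage-fusion-bridge, template switching),
    breakpoint-junction SNP attribution to parental Ty elements, and
    translocation size accounting. A synthetic-data generator produces
    fluctuation cultures, noisy probe-level copy-number profiles, and
    chimeric Ty junction sequences with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    graphics,
    jsonlite,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
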