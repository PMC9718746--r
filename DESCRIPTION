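Package: mosaicY
Title: Single-Cell Detection and Quantification of Sex-Chromosome Mosaicism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and quantifies mosaicism between Y-bearing and
    Y-lacking cell lineages (for example 45,X / 48,XYYY) from droplet
    single-cell RNA-seq UMI counts. Cells are genotyped by presence or
    complete absence of expression from a pseudoautosomal-region-excluded
    Y-linked gene panel; the mosaic fraction is corrected for Y-expression
    dropout calibrated on reference cells. Includes a Monte Carlo
    permutation test for genotype composition across immune cell types
    with Benjamini-Hochberg FDR control, Y/X expression-dosage ratios
    against reference male profiles, per-cell-type Wilcoxon rank-sum
    differential expression with Bonferroni correction and flagging of
    hematological-malignancy-associated genes, Poisson-corrected digital
    droplet PCR (AMELX/AMELY) estimation of the Y-bearing cell fraction,
    and a negative-binomial PBMC simulator with known ground truth for
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    rtracklayer,
    GenomicRanges,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
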