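Package: lofscreen
Title: Common Loss-of-Function Gene Sets, Trait Enrichment, and CRISPR
    Dropout Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for characterizing genes carrying common aggregate
    predicted loss-of-function (pLoF) alleles. Builds a gene set from a
    gene-level table of aggregate pLoF allele frequencies, tests the set
    for trait over-representation against GWAS-catalog-style and
    PheWAS-style association tables using permutation nulls with
    z = (observed - null mean) / null SD, designs paired targeted CRISPR
    knockout sgRNA libraries with non-targeting and safe-harbor controls
    and computes library representation QC, and analyses pooled dropout
    screens: exact-match guide quantification from FASTQ, safe-harbor
    median-of-ratios normalization, a two-group negative-binomial
    depletion test with Benjamini-Hochberg adjustment, gene-level
    significance, and continuous-depletion essentiality calls. A
    synthetic-data generator emulates every input with the statistical
    structure the analyses assume, so the full pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
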