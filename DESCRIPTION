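Package: vqtlscan
Title: Genome-Wide Variance-Heterogeneity Scans for Quantitative Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests for genotype-dependent variance heterogeneity of a
    quantitative trait, a fast screening signature of gene-environment and
    gene-gene interaction (vQTL analysis). Implements the Brown-Forsythe
    (median-based Levene) test for hard genotype calls and a two-stage
    squared-residual regression test (SVLM) that accepts imputed allele
    dosages, together with a simulation framework for estimating type I
    error and power of both tests under an interaction trait model, and
    readers/writers for dosage matrices, VCF dosage fields and scan
    results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    optparse,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
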