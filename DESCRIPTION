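Package: dplus
Title: Windowed D+ Statistics for Detecting Local Introgression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for detecting local introgression between populations with the
    D+ family of four-taxon site-pattern statistics (D, D+, D_ancestral, fd-hat, df).
    Classifies biallelic sites into ABBA/BABA/BAAA/ABAA/BBAA patterns, computes
    count-based and derived-allele-frequency-based statistics in non-overlapping
    genomic windows from VCF input, and calls significant windows against an
    empirical null distribution. Includes closed-form and Monte-Carlo expectations
    of the informative gene-tree branch lengths under an instantaneous
    unidirectional admixture (IUA) model, and a coalescent simulation benchmark
    (precision, recall, false positive rate against introgressed-tract truth)
    driven by the msprime engine.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
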