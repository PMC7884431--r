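Package: rflscan
Title: Discovery of Restorer-of-Fertility RFL Genes and CMS-Associated
    Chimeric Mitochondrial ORFs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for the computational identification of
    nuclear restorer-of-fertility (Rf) candidate genes and of the chimeric
    mitochondrial open reading frames that cause cytoplasmic male sterility
    (CMS) in crops such as wheat. Provides six-frame ORF discovery,
    pentatricopeptide-repeat (PPR) motif scanning and chaining,
    restorer-of-fertility-like (RFL) gene classification, greedy
    identity-based orthogrouping with capture-bait design, phenotype-panel
    candidate selection, pairwise mitochondrial genome comparison with
    chimeric-ORF annotation, PPR-code RNA binding-site prediction, RNA-Seq
    count normalisation and contrast summaries, and coverage-based
    localisation of restorer-induced transcript cleavage sites. A
    synthetic-data module generates inputs with planted ground truth for
    every stage, so the whole pipeline is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    withr
Config/testthat/edition: 3
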