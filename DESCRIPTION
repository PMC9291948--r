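Package: orthoconserv
Title: Cross-Species Conservation of Tissue-Level Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Measures evolutionary conservation of tissue-level gene
    expression between two species from gene-level TPM matrices and
    ortholog tables. Implements 1 - Spearman expression distances with
    Dunnett many-to-one tissue comparisons, a twofold-ratio conservation
    classifier with gene- and gene-set-level conservation tests (exact
    Wilcoxon rank-sum, paired t over replicate pairs), cross-tissue
    intersection of conserved orthologs with late-stage subtraction, and
    GO-term enrichment by two-sided Fisher's exact test with Holm
    correction and anterior/posterior consistency filtering. Includes a
    synthetic two-species data generator with planted conservation
    signals for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    mvtnorm
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    withr,
    jsonlite
Config/testthat/edition: 3
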