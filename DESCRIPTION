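Package: sigsearch
Title: Content-Based Search of Differential Gene-Expression Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Condenses two-group gene-expression comparisons into
    differential-expression (DE) profiles (log fold-change, moderated-t
    p-value, and rank representations), optionally projects them onto a
    reduced feature space derived by independent component analysis, and
    ranks a library of profiles against a query with a p-value-weighted
    Pearson (or Spearman) correlation. Significance is assessed against an
    empirical null of random profile pairs, similarity networks are built at
    an empirical-FDR threshold, and a leave-one-out retrieval harness
    reports ROC/AUC and precision-at-k with a label-permutation null. A
    seeded simulator generates multi-experiment compendia with planted
    differential programs for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, cluster
Suggests: testthat (>= 3.0.0), withr, limma, pROC, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
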