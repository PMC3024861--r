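Package: treegram
Title: Minimum Grammar-Based Compression of Strings and Rooted Labeled Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finds the smallest simple grammar that generates a given string
    (simple context-free grammar), rooted ordered edge-labeled tree (simple
    elementary ordered tree grammar), or rooted unordered edge-labeled tree
    (simple elementary unordered tree grammar) by exact integer linear
    programming. Provides candidate subtree and division enumeration,
    Euler-string canonicalization for subtree isomorphism, grammar
    reconstruction and verification, the polynomial-time TREE-BISECTION
    baseline, and repeated-subtree (motif) extraction aimed at glycan
    tree structures read from edge lists or KEGG KCF records.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, Matrix, jsonlite, stats, utils
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
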