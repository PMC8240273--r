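Package: lrsolve
Title: Exact Solvers for the Longest Run Subsequence Problem
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the longest run subsequence (LRS) problem: given a
    string over a finite alphabet, find a longest subsequence that contains
    at most one maximal run per symbol. Provides run-length instance
    handling, provably safe prefix and infix reduction rules, an exact
    dynamic program that is fixed-parameter tractable in the alphabet size,
    an exact 0/1 integer linear program solved by a built-in branch-and-bound
    backend, a brute-force reference solver, and a hybrid dispatcher that
    picks an algorithm from instance shape. Includes a reduction from the
    linear ordering problem that realizes the NP-hardness construction as a
    self-verifying harness, synthetic instance generators, and an adapter
    that turns binned contig-to-contig alignments (PAF) into contig
    orderings for homology-based scaffolding.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
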