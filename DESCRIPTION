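Package: srhtest
Title: Matched-Pairs Tests of Symmetry for Model Violation in Sequence Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests whether aligned sequences are consistent with evolution
    under stationary, reversible, and homogeneous (SRH) substitution
    processes. Implements the matched-pairs tests of homogeneity on pairwise
    divergence matrices (Bowker's test of symmetry, Stuart's test of marginal
    symmetry, and the internal-symmetry test), extends them to whole
    alignment partitions through the maximum-divergence pair (the MaxSymTest
    family), and classifies partitions into passing and failing sets that can
    be concatenated and re-analysed separately. Also provides topology-only
    tree comparison metrics (path difference, normalized path difference
    against a uniform random-topology null, and quartet distance) to quantify
    the effect of removing failing partitions on inferred trees, and a
    continuous-time Markov simulator for generating alignments under SRH
    conditions and under controlled nonstationary or nonhomogeneous
    violations.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    seqinr,
    stats,
    utils
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
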