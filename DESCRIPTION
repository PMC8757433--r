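Package: retempl
Title: Canonicalization, Hierarchical Correction, and Evaluation of Reaction Templates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for curating retrosynthesis reaction-template libraries
    encoded as restricted (And-only) SMARTS pairs connected by atom mapping.
    Templates are canonicalized by Weisfeiler-Lehman refinement on a condensed
    reactant/product graph with individualization-refinement tie-breaking,
    giving a unique string per chemical transformation; duplicate templates
    are merged and nonexclusive templates (one subsuming another by subgraph
    isomorphism) are removed by a hierarchical, cluster-wise correction that
    keeps only the most general member of each exclusivity tree. Includes a
    template application engine for small molecules, ranking metrics
    (top-N accuracy under exact-template and exact-precursor criteria,
    applicability, outcome-averaged accuracy), a fingerprint-similarity
    baseline ranker, and a synthetic corpus generator with known ground truth
    for benchmarking the correction pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
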