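Package: compmatch
Title: Composition-Matching Proteome Searches for Intrinsically
    Disordered Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Searches whole proteomes for the nearest compositional
    matches to a query protein region. Every protein is scanned with a
    range of window sizes, each window is scored against the query's
    percent amino-acid composition with a Manhattan (or Euclidean)
    distance, and proteins are ranked by the compositional identity of
    their single best window. Intended for intrinsically disordered
    regions and prion-like domains, whose in vivo activity is often
    governed by bulk composition rather than residue order. Also
    provides all-vs-all comparison matrices combining compositional
    identity with global-alignment percent identity, rank-robustness
    utilities across window sizes and distance metrics, seeded synthetic
    proteome generators with planted composition-matched regions, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
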