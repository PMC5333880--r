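Package: petrinv
Title: Invariant, MCT-Set, Clustering and Knockout Analysis of Qualitative Petri Nets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the qualitative analysis of discrete Petri net models of
    biomolecular networks. Builds incidence matrices and runs the token game,
    computes minimal t- and p-invariants by the Fourier-Motzkin/Farkas tableau
    method, partitions transitions into maximal common transition (MCT) sets,
    clusters t-invariant supports over a grid of distance metrics and linkage
    methods scored with a Mean Split Silhouette style index, and performs both
    structural (invariant-based) and dynamic (stochastic token-game simulation)
    knockout analysis. Reads and writes Snoopy SPPED, PNML, a native JSON
    dialect and CSV matrices, and ships a support-matrix fixture for a
    published angiogenesis model.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    cluster,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
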