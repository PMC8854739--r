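Package: phfold
Title: Topological Data Analysis of Protein Folding Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing protein folding trajectories through the lens
    of persistent homology. Computes degree-1 persistent homology of C-alpha
    point clouds under an alpha-complex filtration, extracts volume-optimal
    representative cycles, vectorizes them as "bag of simplices" edge weights,
    reduces dimension by non-negative matrix factorization with residual- and
    cophenetic-based rank selection, and estimates grid-binned flow fields of
    the folding dynamics in the reduced space. Includes a synthetic
    three-helix bead-chain trajectory generator so the full pipeline can be
    exercised and validated without external molecular-dynamics data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    withr,
    bio3d,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
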