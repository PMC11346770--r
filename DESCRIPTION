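Package: scacn
Title: Allele-Specific Copy Number Calling for Low-Coverage Single-Cell
    DNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Calls allele-specific copy numbers and cell ploidies from
    cell-by-bin read-count and B-allele-frequency matrices produced by
    low-coverage single-cell whole-genome sequencing. Segmentation combines a
    global Gaussian mixture model over the joint read-depth-ratio / mirrored
    BAF feature space (EM fit, BIC model selection, weighted component
    merging) with per-cell circular binary segmentation, reconciled by a
    cross-cell breakpoint frequency filter. Ploidy is selected among
    whole-genome-duplication-aware candidates by a weighted Bayesian
    information criterion, and integer allele-specific states are assigned by
    likelihood over a bounded state space. Includes a clone-tree simulator of
    ground-truthed count/BAF matrices and evaluation metrics (log-scaled
    sum-of-squares error, tolerance-aware breakpoint precision/recall via
    maximum bipartite matching, ploidy agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
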