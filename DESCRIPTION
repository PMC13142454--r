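Package: tiratlas
Title: Cross-Kingdom TIR Domain Atlas Construction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds atlases of Toll/interleukin-1 receptor (TIR) domain
    diversity from protein sequence databases. Implements iterative
    profile-based homology search with Gumbel-calibrated E-values and
    saturation stopping, domain envelope calling with overlap resolution,
    greedy phylogenetic-diversity downsampling with per-group caps,
    consensus clade definition across replicate trees, secondary-structure
    fold validation of candidate domains, and Dollo/count-parsimony
    reconstruction of gene-family gain and loss on a species tree. A
    synthetic-data module generates every pipeline input with planted
    ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    bio3d,
    Biostrings,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
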