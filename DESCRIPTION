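Package: zdnaphylo
Title: Z-DNA and Short Tandem Repeat Density Evolution Across Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects Z-DNA-prone motifs (maximal alternating
    purine/pyrimidine tracts) and perfect short tandem repeats in genome
    assemblies, computes per-species motif densities, profiles motif
    positions in 10-kb windows upstream of start codons with a
    Lilliefors/Friedman/Nemenyi test battery, and relates densities to
    life-history traits with phylogenetic comparative methods implemented
    from first principles: Brownian-motion, Ornstein-Uhlenbeck,
    early-burst and Pagel's lambda covariances, profile-likelihood
    fitting with AICc model selection, maximum-likelihood ancestral state
    reconstruction, and phylogenetic generalized least squares with
    parametric bootstrap. Ships seeded simulators for genomes with
    planted motifs, annotations, Yule trees and traits so every stage
    can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    nlme,
    nortest,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
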