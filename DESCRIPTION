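Package: sdmphylo
Title: Structure-Based Phylogenetics of Protein Domains via a Structural
    Dissimilarity Metric
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers phylogenies of distantly related protein domains from
    their three-dimensional structures. Pairwise C-alpha superposition with
    a 3 Angstrom topological-equivalence criterion feeds a structural
    dissimilarity metric (SDM) combining the proportion of topologically
    equivalent residues and a scaled RMSD; all-pairs SDM matrices are fed
    to clock-constrained Fitch-Margoliash least-squares, neighbor-joining
    and UPGMA tree inference, with cluster extraction, Robinson-Foulds
    comparison against sequence-based trees, and a synthetic benchmark
    generator that diverges C-alpha traces along a known guide tree.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    bio3d,
    Biostrings,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    pracma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
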