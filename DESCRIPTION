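Package: relclust
Title: Linear-Time Clustering of Biological Sequences by Relatedness Sorting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Threshold-based inexact clustering of nucleotide and amino-acid
    sequences with linear asymptotic time complexity. Input sequences are
    first separated into partitions of detectable homology by counting rare
    k-mers selected through hashing, then iteratively sorted by relatedness
    using one-dimensional projections of relative k-mer distances, and
    finally assigned greedily to cluster representatives using candidates
    drawn from rare-k-mer sharing and rank proximity. Pairwise similarity is
    estimated from collinear k-mer anchor chains and confirmed by anchored
    affine-gap alignment. Includes a synthetic sequence-family generator and
    clustering evaluation metrics (normalized and adjusted mutual
    information, label consistency, threshold-violation rate, empirical
    scaling exponents).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    graphics,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    igraph,
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
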