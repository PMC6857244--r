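Package: bandclust
Title: Adjacency-Constrained Hierarchical Clustering of Band Similarity
    Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quasi-linear adjacency-constrained hierarchical agglomerative
    clustering with Ward's linkage for similarity matrices that are (or can
    be assumed to be) band matrices, as arise when segmenting chromosomes
    from locus-level data.  Ward linkages are evaluated in constant time
    from precomputed pencil-shaped cumulative sums, and candidate fusions
    between adjacent clusters are kept in a binary min-heap with lazy
    invalidation, giving O(p(h + log p)) time and O(ph) space for p loci
    and bandwidth h.  Includes a quadratic reference implementation,
    model selection by the broken-stick rule and the slope heuristic,
    dendrogram comparison by the first-difference index, adapters building
    band similarities from SNP genotypes (linkage-disequilibrium r2) and
    Hi-C contact maps (log counts), BED/GRanges export of contiguous
    clusters, seeded synthetic-data generators with planted block
    structure, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Matrix,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    vcfR,
    rtracklayer,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllGenerics.R'
    'BandSimilarity-class.R'
    'PencilSums-class.R'
    'Dendrogram-class.R'
    'FusionHeap.R'
    'RcppExports.R'
    'bandclust-package.R'
    'genomics.R'
    'synthetic.R'
    'model-selection.R'
    'cluster.R'
    'cli.R'
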