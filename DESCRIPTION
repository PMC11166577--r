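Package: pixelgraph
Title: Spatial Proteomics of Single Cells from DNA-Pixel Sequencing Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end processing of molecular pixelation experiments, an
    optics-free spatial proteomics assay in which antibody-oligonucleotide
    conjugates on single cells are associated into overlapping DNA-pixel
    neighborhoods and sequenced. Converts amplicon reads carrying a UMI,
    a protein barcode and two unique pixel identifiers into deduplicated,
    error-corrected edge lists; assembles per-cell bipartite graphs, removes
    spurious inter-cell edges by Leiden community detection, calls and filters
    cell components and exports count matrices; computes graph-spatial
    statistics (Moran's I polarity scores and permutation-based colocalization
    scores on one-mode pixel projections), differential comparisons and CLR
    gating; produces 3D layouts, sphere projections and density heatmaps.
    Includes a ground-truth simulator of pixelation experiments (cells as unit
    spheres, von Mises-Fisher marker placement, pixel zones, PCR duplication
    and sequencing error) so the whole pipeline is testable without data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    igraph,
    jsonlite,
    Matrix,
    methods,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
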