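Package: omnimat
Title: Representation-Agnostic Access to Dense, Sparse and HDF5-Backed Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A single accessor contract over the matrix representations used
    for large biological data sets: in-memory dense arrays, compressed
    sparse column (CSC) matrices, and chunked HDF5-backed matrices.
    Row, column and entry access behave identically across backends under a
    copy-on-access contract. Includes a cached row-access algorithm for CSC
    matrices that avoids redundant binary searches during consecutive or
    ordered row sweeps, automatic HDF5 chunk-cache tuning and chunk-layout
    selection for sequential or random access, streamed rechunking of HDF5
    datasets under a memory budget, representation-matched output builders,
    sparsity-exploiting matrix multiplication, single-cell RNA-seq style
    quality-control metrics, a seeded matrix simulator, and a
    hardware-independent benchmark harness based on probe and chunk-fetch
    counts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    Rcpp
LinkingTo: Rcpp
SystemRequirements: HDF5 (libhdf5)
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
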