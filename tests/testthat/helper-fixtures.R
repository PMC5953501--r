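# Shared fixtures. The 3x3 worked example used throughout:
#   1 0 0
#   0 0 3
#   2 0 4
m3Matrix <- function() matrix(c(1, 0, 2, 0, 0, 0, 0, 3, 4), nrow = 3)

# write a handle to a temporary HDF5 file and reopen it
asTempH5 <- function(h, layout = NULL) {
    f <- tempfile(fileext = ".h5")
    writeMatrix(h, f, layout = layout)
    openMatrix(f)
}

# all backends that can represent a dense R matrix of this element type
backendTrio <- function(m, h5layout = NULL) {
    d <- openMatrix(m)
    out <- list(dense = d)
    if (!is.character(m)) out$sparse_csc <- cscFromDense(m)
    out$hdf5 <- asTempH5(d, layout = h5layout)
    out
}

# deterministic dense fixture of any element type
randomDense <- function(nrow, ncol, elemtype, density, seed) {
    as.matrix(simulateDense(nrow, ncol, elemtype = elemtype,
                            density = if (elemtype == "string") 1 else density,
                            seed = seed))
}

# strided visit order: every `stride`-th index, returning to the first
# unvisited (1, 1+s, ..., 2, 2+s, ...)
stridedOrder <- function(n, stride = 5L) {
    n <- as.integer(n)
    stride <- as.integer(stride)
    unlist(lapply(seq_len(min(stride, n)), function(s) seq.int(s, n, stride)))
}
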