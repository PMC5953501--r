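# Representation-agnostic computations. Everything here reaches the data
# through the accessor contract only -- no backend peeking -- so results
# are identical across dense, sparse and HDF5 handles. Accumulation is in
# double precision for every numeric element type, so integer count
# matrices cannot overflow 32-bit sums.

checkNumericHandle <- function(h) {
    if (elemType(h) == "string")
        stop("operation requires a numeric element type")
}

#' Column and row sums through the accessor contract
#'
#' @param x a numeric [MatrixHandle-class].
#' @param na.rm,dims ignored (handles never hold missing values; present
#'   for generic compatibility).
#' @return double vector of per-column (per-row) sums.
#' @examples
#' h <- openMatrix(matrix(c(1, 0, 2, 0, 0, 0, 0, 3, 4), nrow = 3))
#' colSums(h)   # 3 0 7
#' rowSums(h)   # 1 3 6
#' @export
setMethod("colSums", "MatrixHandle", function(x, na.rm = FALSE, dims = 1) {
    checkNumericHandle(x)
    vapply(seq_len(x@ncol),
           function(c) sum(as.double(getCol(x, c))), numeric(1))
})

#' @rdname colSums-MatrixHandle-method
#' @export
setMethod("rowSums", "MatrixHandle", function(x, na.rm = FALSE, dims = 1) {
    checkNumericHandle(x)
    out <- numeric(x@nrow)
    for (c in seq_len(x@ncol)) out <- out + as.double(getCol(x, c))
    out
})

#' Quality-control metrics for count matrices
#'
#' @description
#' The per-gene and per-cell summaries routinely computed on single-cell
#' RNA-seq count matrices, under the genes-in-rows convention (each row a
#' gene, each column a cell):
#' \itemize{
#'   \item library size: total counts in each cell (a column sum);
#'   \item cells per gene: number of cells in which a gene is detected,
#'     i.e. has a strictly positive count;
#'   \item genes per cell: number of genes detected in each cell;
#'   \item nonzero fraction: stored nonzeros over all entries.
#' }
#' All quantities are computed through the accessor contract, one column
#' sweep, so any backend gives identical reports. Conservation holds by
#' construction: column sums and row sums total the same grand sum, and
#' both detection counts total the number of nonzero entries.
#'
#' @param h a numeric [MatrixHandle-class].
#' @param genesInRows `TRUE` (default) if rows are genes and columns are
#'   cells; `FALSE` flips the orientation.
#' @return a [MetricsReport-class].
#' @examples
#' m3 <- openMatrix(matrix(c(1, 0, 2, 0, 0, 0, 0, 3, 4), nrow = 3))
#' rep <- qcMetrics(m3)
#' librarySizes(rep)    # 3 0 7
#' cellsPerGene(rep)    # 1 1 2
#' genesPerCell(rep)    # 2 0 2
#' nonzeroFraction(rep) # 4/9
#' @export
qcMetrics <- function(h, genesInRows = TRUE) {
    checkNumericHandle(h)
    nr <- nrow(h); nc <- ncol(h)
    csums <- numeric(nc)
    cnnz <- integer(nc)
    rsums <- numeric(nr)
    rnnz <- integer(nr)
    sawNegative <- FALSE
    for (c in seq_len(nc)) {
        v <- as.double(getCol(h, c))
        if (!sawNegative && any(v < 0)) sawNegative <- TRUE
        csums[c] <- sum(v)
        pos <- v != 0
        cnnz[c] <- sum(pos)
        rsums <- rsums + v
        rnnz <- rnnz + (v > 0)
    }
    if (sawNegative)
        warning("negative entries found; count-matrix metrics assume nonnegative data")
    nnz <- sum(cnnz)
    frac <- if (nr > 0L && nc > 0L) nnz / (as.double(nr) * nc) else 0
    if (genesInRows) {
        new("MetricsReport", colSums = csums, rowSums = rsums,
            librarySizes = csums, cellsPerGene = as.integer(rnnz),
            genesPerCell = cnnz, nonzeroFraction = frac,
            genesInRows = TRUE, dims = c(nr, nc))
    } else {
        new("MetricsReport", colSums = csums, rowSums = rsums,
            librarySizes = rsums, cellsPerGene = cnnz,
            genesPerCell = as.integer(rnnz), nonzeroFraction = frac,
            genesInRows = FALSE, dims = c(nr, nc))
    }
}

#' Container for count-matrix QC metrics
#'
#' @description Produced by [qcMetrics()]. Accessors: [librarySizes()],
#' [cellsPerGene()], [genesPerCell()], [nonzeroFraction()],
#' [metricColSums()], [metricRowSums()].
#'
#' @slot colSums,rowSums per-column / per-row totals (double).
#' @slot librarySizes per-cell totals.
#' @slot cellsPerGene,genesPerCell detection counts (integer).
#' @slot nonzeroFraction fraction of entries that are nonzero.
#' @slot genesInRows orientation flag.
#' @slot dims matrix dimensions.
#' @exportClass MetricsReport
setClass("MetricsReport", representation(
    colSums = "numeric", rowSums = "numeric", librarySizes = "numeric",
    cellsPerGene = "integer", genesPerCell = "integer",
    nonzeroFraction = "numeric", genesInRows = "logical", dims = "integer"))

setValidity("MetricsReport", function(object) {
    tol <- 1e-9 * max(1, abs(sum(object@colSums)))
    if (abs(sum(object@colSums) - sum(object@rowSums)) > tol)
        return("column sums and row sums do not conserve the grand total")
    if (sum(object@cellsPerGene) != sum(object@genesPerCell))
        return("detection counts do not total the same nonzero count")
    if (object@nonzeroFraction < 0 || object@nonzeroFraction > 1)
        return("nonzero fraction outside [0, 1]")
    TRUE
})

setMethod("show", "MetricsReport", function(object) {
    cat(sprintf(
        "<MetricsReport> %d x %d (%s), %d nonzero (%.3g%%)\n",
        object@dims[1], object@dims[2],
        if (object@genesInRows) "genes x cells" else "cells x genes",
        sum(object@genesPerCell), 100 * object@nonzeroFraction))
    invisible(NULL)
})

#' @rdname qcMetrics
#' @param report a `MetricsReport`.
#' @export
librarySizes <- function(report) report@librarySizes
#' @rdname qcMetrics
#' @export
cellsPerGene <- function(report) report@cellsPerGene
#' @rdname qcMetrics
#' @export
genesPerCell <- function(report) report@genesPerCell
#' @rdname qcMetrics
#' @export
nonzeroFraction <- function(report) report@nonzeroFraction
#' @rdname qcMetrics
#' @export
metricColSums <- function(report) report@colSums
#' @rdname qcMetrics
#' @export
metricRowSums <- function(report) report@rowSums

#' Serialise a metrics report to TSV
#'
#' One summary comment line (dimensions, nonzero count and fraction)
#' followed by a long table with one row per gene and per cell: columns
#' `section` (`gene`/`cell`), `index` (1-based), `total` (row or library
#' sum) and `detected` (cells expressing the gene / genes detected in the
#' cell).
#'
#' @param report a `MetricsReport`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeMetricsTSV <- function(report, path) {
    con <- file(path, "w")
    on.exit(close(con))
    gsums <- if (report@genesInRows) report@rowSums else report@colSums
    csums <- report@librarySizes
    writeLines(sprintf(
        "# dims=%dx%d nnz=%d nonzero_fraction=%.10g",
        report@dims[1], report@dims[2], sum(report@genesPerCell),
        report@nonzeroFraction), con)
    writeLines("section\tindex\ttotal\tdetected", con)
    if (length(report@cellsPerGene))
        writeLines(sprintf("gene\t%d\t%.10g\t%d",
                           seq_along(report@cellsPerGene), gsums,
                           report@cellsPerGene), con)
    if (length(report@genesPerCell))
        writeLines(sprintf("cell\t%d\t%.10g\t%d",
                           seq_along(report@genesPerCell), csums,
                           report@genesPerCell), con)
    invisible(path)
}

# ---- multiplication ----

#' Matrix multiplication through the accessor contract
#'
#' @description
#' `matmulNaive()` computes `A %*% B` by the definition, reading rows of
#' `A` and columns of `B` through the accessors, so it works for any
#' backend pair; the result representation follows
#' [matchOutputRepresentation()] on `A`'s representation (with double
#' elements).
#'
#' `matmulSparse()` is the sparsity-exploiting variant for CSC operands
#' (Gustavson's method): for each column `j` of `B`, each stored entry
#' `B[k, j]` scatter-adds `B[k, j]` times the stored entries of column `k`
#' of `A` into a dense accumulator, which is then compacted into the
#' output column. No zero entry of either operand is ever touched, so the
#' multiply-add count equals `sum_j sum_k nnz(A[, k])` over stored
#' `B[k, j]` -- far below `nrow * ncol * inner` at low density.
#'
#' @param A,B conformable numeric handles (`matmulSparse()` requires
#'   [SparseMatrixHandle-class] operands, or dense handles which are first
#'   compacted to CSC).
#' @param counter optional [newProbeCounter()]; `matmulSparse()` adds its
#'   multiply-add count to `multiplyAdds`.
#' @param dest destination file when the matched output representation is
#'   HDF5 (default: a tempfile).
#' @return the product as a handle: `matmulNaive()` in the matched
#'   representation, `matmulSparse()` always sparse CSC (double).
#' @examples
#' m3 <- matrix(c(1, 0, 2, 0, 0, 0, 0, 3, 4), nrow = 3)
#' p <- matmulSparse(cscFromDense(m3), cscFromDense(m3))
#' as.matrix(p)   # rows: 1 0 0 / 6 0 12 / 10 0 16
#' @export
matmulNaive <- function(A, B, dest = NULL) {
    checkNumericHandle(A); checkNumericHandle(B)
    if (ncol(A) != nrow(B))
        stop("non-conformable: A is ", nrow(A), " x ", ncol(A),
             ", B is ", nrow(B), " x ", ncol(B))
    spec <- matchOutputRepresentation(repType(A), "double")
    b <- makeBuilder(spec, nrow(A), ncol(B), dest = dest)
    bcols <- lapply(seq_len(ncol(B)), function(c) as.double(getCol(B, c)))
    out <- numeric(ncol(B))
    for (r in seq_len(nrow(A))) {
        arow <- as.double(getRow(A, r))
        for (c in seq_len(ncol(B))) out[c] <- sum(arow * bcols[[c]])
        builderSetRow(b, r, out)
    }
    finalizeBuilder(b)
}

#' @rdname matmulNaive
#' @export
matmulSparse <- function(A, B, counter = NULL) {
    if (is(A, "DenseMatrixHandle")) A <- cscFromDense(A)
    if (is(B, "DenseMatrixHandle")) B <- cscFromDense(B)
    stopifnot(is(A, "SparseMatrixHandle"), is(B, "SparseMatrixHandle"))
    if (ncol(A) != nrow(B))
        stop("non-conformable: A is ", nrow(A), " x ", ncol(A),
             ", B is ", nrow(B), " x ", ncol(B))
    nr <- nrow(A)
    outI <- vector("list", ncol(B))
    outX <- vector("list", ncol(B))
    counts <- integer(ncol(B))
    madds <- 0
    acc <- numeric(nr)
    for (j in seq_len(ncol(B))) {
        lo <- B@p[j] + 1L
        hi <- B@p[j + 1L]
        if (hi < lo) next
        acc[] <- 0
        for (t in lo:hi) {
            k <- B@i[t] + 1L       # inner index: column of A
            alo <- A@p[k] + 1L
            ahi <- A@p[k + 1L]
            if (ahi < alo) next
            rows <- A@i[alo:ahi] + 1L
            acc[rows] <- acc[rows] + B@x[t] * A@x[alo:ahi]
            madds <- madds + (ahi - alo + 1L)
        }
        nz <- which(acc != 0)
        if (length(nz)) {
            outI[[j]] <- nz - 1L
            outX[[j]] <- acc[nz]
            counts[j] <- length(nz)
        }
    }
    if (!is.null(counter))
        counter$multiplyAdds <- counter$multiplyAdds + madds
    p <- c(0L, cumsum(counts))
    newSparseHandle(unlist(outX) %||% numeric(0),
                    unlist(outI) %||% integer(0),
                    p, nr, ncol(B), "double")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
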