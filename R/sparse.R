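# Compressed sparse column backend with cached row access.
#
# Row access on a CSC store requires locating the requested row within each
# column's sorted index run. The naive method binary-searches every column
# from scratch on every request. The cached method keeps, per column, the
# offset of the first stored index not below the previously served row;
# consecutive requests then advance that pointer linearly (stepping past
# each stored element at most once over a full ascending sweep), ordered
# jumps search only above the pointer, and backward jumps search only below
# it. Both paths return identical values for every access sequence; they
# differ only in the number of row-index comparisons performed.

# returns NULL if the arrays form a valid CSC store, else a message
cscViolation <- function(x, i, p, nrow, ncol, elemtype) {
    if (!elemtype %in% c("integer", "logical", "double"))
        return("sparse strings unsupported")
    if (length(p) != ncol + 1L)
        return(sprintf("p has length %d, expected ncol + 1 = %d",
                       length(p), ncol + 1L))
    if (anyNA(x) || anyNA(i) || anyNA(p))
        return("missing values are not supported")
    if (length(p) && p[1L] != 0L)
        return("p[1] must be 0")
    if (is.unsorted(p)) {
        bad <- which(diff(p) < 0L)[1L]
        return(sprintf("p not nondecreasing at column %d", bad))
    }
    if (length(p) && p[length(p)] != length(x))
        return(sprintf("last element of p is %d but %d values are stored",
                       p[length(p)], length(x)))
    if (length(i) != length(x))
        return("i and x lengths differ")
    if (length(i)) {
        if (min(i) < 0L || max(i) >= nrow) {
            bad <- which(i < 0L | i >= nrow)[1L]
            return(sprintf("row index out of range at offset %d", bad - 1L))
        }
        for (c in seq_len(ncol)) {
            lo <- p[c] + 1L
            hi <- p[c + 1L]
            if (hi > lo && is.unsorted(i[lo:hi], strictly = TRUE))
                return(sprintf(
                    "row indices not strictly increasing in column %d", c))
        }
        if (any(x == 0))
            return(sprintf("stored zero at offset %d", which(x == 0)[1L] - 1L))
        if (elemtype == "logical" && any(x != 1))
            return("logical store holds values other than 1")
        if (elemtype == "integer" && any(x != trunc(x)))
            return("integer store holds non-integer values")
    }
    NULL
}

freshRowCache <- function(p, ncol) {
    cache <- new.env(parent = emptyenv())
    cache$ptr <- p[-1L]         # lower bound of "no history": column ends
    cache$lastRow <- -1L        # sentinel: no previous row
    cache
}

newSparseHandle <- function(x, i, p, nrow, ncol, elemtype) {
    h <- new("SparseMatrixHandle", nrow = as.integer(nrow),
             ncol = as.integer(ncol), elemtype = elemtype,
             x = as.double(x), i = as.integer(i), p = as.integer(p),
             cache = new.env(parent = emptyenv()))
    h@cache$ptr <- h@p[-1L]
    h@cache$lastRow <- -1L
    h
}

sparseFromTriplets <- function(i, j, x, nrow, ncol, elemtype) {
    # i, j 1-based triplets, any order; duplicates are the caller's problem
    ord <- order(j, i)
    i <- i[ord]; j <- j[ord]; x <- x[ord]
    keep <- x != 0
    i <- i[keep]; j <- j[keep]; x <- x[keep]
    p <- c(0L, cumsum(tabulate(j, nbins = ncol)))
    newSparseHandle(x, i - 1L, p, nrow, ncol, elemtype)
}

#' Build a CSC store from a dense matrix
#'
#' Scans a dense matrix in column-major order and records its nonzero
#' entries in the three-array compressed sparse column encoding (values
#' `x`, 0-based row indices `i`, column offsets `p`). Reconstructing the
#' dense matrix from the result reproduces the input exactly.
#'
#' @param d a base R matrix or a `DenseMatrixHandle`, with integer, logical
#'   or double elements (sparse string matrices are not supported).
#' @return a [SparseMatrixHandle-class].
#' @examples
#' m3 <- matrix(c(1, 0, 2, 0, 0, 0, 0, 3, 4), nrow = 3)
#' s <- cscFromDense(m3)
#' cscArrays(s)  # x = 1 2 3 4; i = 0 2 1 2; p = 0 2 2 4
#' @export
cscFromDense <- function(d) {
    if (is(d, "DenseMatrixHandle")) {
        et <- d@elemtype
        m <- as.matrix(d)
    } else if (is.matrix(d)) {
        et <- elemTypeOf(d)
        m <- d
    } else stop("expected a matrix or DenseMatrixHandle")
    if (et == "string") stop("sparse strings unsupported")
    if (anyNA(m)) stop("missing values are not supported")
    nz <- which(m != 0)  # column-major order by construction
    i0 <- (nz - 1L) %% nrow(m)
    j1 <- (nz - 1L) %/% nrow(m) + 1L
    p <- c(0L, cumsum(tabulate(j1, nbins = ncol(m))))
    newSparseHandle(as.double(m[nz]), i0, p, nrow(m), ncol(m), et)
}

#' Validate the CSC invariants of a sparse handle
#'
#' Checks the structural invariants of the compressed sparse column
#' encoding: `p` starts at zero, is nondecreasing and ends at the number of
#' stored values; row indices are in range and strictly increasing within
#' each column; stored values are nonzero (and 1 for logical stores).
#'
#' @param s a [SparseMatrixHandle-class], or a list with fields `x`, `i`,
#'   `p`, `nrow`, `ncol` (and optionally `elemtype`) to check raw arrays.
#' @return `TRUE` if valid, otherwise a character string describing the
#'   first violated invariant and its location.
#' @examples
#' validateCSC(cscFromDense(matrix(1:4, 2)))  # TRUE
#' validateCSC(list(x = 1, i = 5L, p = c(0L, 1L), nrow = 3, ncol = 1))
#' @export
validateCSC <- function(s) {
    if (is(s, "SparseMatrixHandle")) {
        msg <- cscViolation(s@x, s@i, s@p, s@nrow, s@ncol, s@elemtype)
    } else if (is.list(s)) {
        et <- if (is.null(s$elemtype)) "double" else s$elemtype
        msg <- cscViolation(s$x, as.integer(s$i), as.integer(s$p),
                            s$nrow, s$ncol, et)
    } else stop("expected a SparseMatrixHandle or a list of CSC arrays")
    if (is.null(msg)) TRUE else msg
}

#' Raw CSC arrays of a sparse handle
#'
#' @param s a [SparseMatrixHandle-class].
#' @return list with `x` (values), `i` (0-based row indices), `p` (column
#'   offsets, length `ncol + 1`).
#' @export
cscArrays <- function(s) {
    stopifnot(is(s, "SparseMatrixHandle"))
    list(x = castToElem(s@x, if (s@elemtype == "logical") "double"
                             else s@elemtype),
         i = s@i, p = s@p)
}

#' @rdname accessors
#' @export
setMethod("getCol", "SparseMatrixHandle",
    function(x, c, first = 1L, last = NULL, counter = NULL) {
        c <- checkIndex(c, x@ncol, "column")
        ext <- checkExtent(first, last, x@nrow)
        n <- ext[2] - ext[1] + 1L
        out <- numeric(max(n, 0L))
        lo <- x@p[c] + 1L
        hi <- x@p[c + 1L]
        if (hi >= lo && n > 0L) {
            rows <- x@i[lo:hi] + 1L
            keep <- rows >= ext[1] & rows <= ext[2]
            out[rows[keep] - ext[1] + 1L] <- x@x[lo:hi][keep]
        }
        castToElem(out, x@elemtype)
    })

#' @rdname accessors
#' @export
setMethod("getRow", "SparseMatrixHandle",
    function(x, r, first = 1L, last = NULL, counter = NULL) {
        r <- checkIndex(r, x@nrow, "row")
        ext <- checkExtent(first, last, x@ncol)
        if (ext[2] < ext[1]) return(castToElem(numeric(0), x@elemtype))
        if (ext[1] != 1L || ext[2] != x@ncol) {
            # partial extents would desynchronise the per-column pointers
            # from the cached last-row state; fall back to the naive search
            # without touching the cache
            res <- .cpp_csc_row_naive(x@x, x@i, x@p, r - 1L,
                                      ext[1] - 1L, ext[2])
            countProbes(counter, probes = res$probes)
            return(castToElem(res$values, x@elemtype))
        }
        res <- .cpp_csc_row_cached(x@x, x@i, x@p, r - 1L, 0L, x@ncol,
                                   x@cache$ptr, x@cache$lastRow)
        x@cache$ptr <- res$ptr
        x@cache$lastRow <- r - 1L
        countProbes(counter, probes = res$probes)
        castToElem(res$values, x@elemtype)
    })

#' Naive binary-search row access for sparse handles
#'
#' The uncached reference path: for every column, a fresh lower-bound
#' binary search of the requested row over the column's full index run.
#' Serves as the oracle the cached path ([getRow()] on a sparse handle) is
#' verified against, and as the baseline for probe-count comparisons.
#'
#' @inheritParams accessors
#' @return vector of the handle's element type, as [getRow()].
#' @examples
#' s <- cscFromDense(matrix(c(1, 0, 2, 0, 0, 0, 0, 3, 4), nrow = 3))
#' sparseRowNaive(s, 2)   # 0 0 3
#' @export
sparseRowNaive <- function(x, r, first = 1L, last = NULL, counter = NULL) {
    stopifnot(is(x, "SparseMatrixHandle"))
    r <- checkIndex(r, x@nrow, "row")
    ext <- checkExtent(first, last, x@ncol)
    if (ext[2] < ext[1]) return(castToElem(numeric(0), x@elemtype))
    res <- .cpp_csc_row_naive(x@x, x@i, x@p, r - 1L, ext[1] - 1L, ext[2])
    countProbes(counter, probes = res$probes)
    castToElem(res$values, x@elemtype)
}

#' @rdname accessors
#' @export
setMethod("getElem", "SparseMatrixHandle",
    function(x, r, c, counter = NULL) {
        r <- checkIndex(r, x@nrow, "row")
        c <- checkIndex(c, x@ncol, "column")
        lo <- x@p[c] + 1L
        hi <- x@p[c + 1L]
        out <- 0
        if (hi >= lo) {
            run <- x@i[lo:hi]
            pos <- findInterval(r - 1L, run)
            if (pos >= 1L && run[pos] == r - 1L) out <- x@x[lo + pos - 1L]
        }
        castToElem(out, x@elemtype)
    })

#' @rdname accessors
#' @export
setMethod("getColView", "SparseMatrixHandle", function(x, c) {
    c <- checkIndex(c, x@ncol, "column")
    lo <- x@p[c] + 1L
    hi <- x@p[c + 1L]
    idx <- if (hi >= lo) lo:hi else integer(0)
    structure(list(values = castToElem(x@x[idx], x@elemtype),
                   rows = x@i[idx] + 1L, nrow = x@nrow),
              class = "sparseColumnView")
})

#' @rdname accessors
#' @export
setMethod("getColView", "HDF5MatrixHandle", function(x, c) {
    stop("views unsupported for file-backed matrices")
})

# ---- full row sweeps (benchmark backbone) ----

#' Instrumented full row sweep over a sparse handle
#'
#' Visits the listed rows (every column of each) through the cached or the
#' naive row-access path, entirely in compiled code, and reports the total
#' probe count of the sweep. The cached variant starts from a fresh row
#' cache, so counts depend only on the store and the visit order.
#'
#' @param s a [SparseMatrixHandle-class].
#' @param order 1-based row indices in visit order.
#' @param method `"cached"` or `"naive"`.
#' @return list with `rowTotals` (the sum of each visited row, a cheap
#'   fingerprint for oracle comparison) and `probes` (row-index
#'   comparisons performed).
#' @examples
#' s <- simulateSparse(200, 30, density = 0.05, seed = 1)
#' sparseSweep(s, seq_len(200), "cached")$probes
#' @export
sparseSweep <- function(s, order, method = c("cached", "naive")) {
    stopifnot(is(s, "SparseMatrixHandle"))
    method <- match.arg(method)
    ord0 <- as.integer(order) - 1L
    if (length(ord0) && (min(ord0) < 0L || max(ord0) >= s@nrow))
        stop("sweep order contains out-of-range rows")
    f <- if (method == "cached") .cpp_csc_sweep_cached else .cpp_csc_sweep_naive
    res <- f(s@x, s@i, s@p, s@ncol, ord0)
    list(rowTotals = res$row_totals, probes = res$probes)
}
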