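# Dense backend: a flat column-major vector. Entry (r, c) with 1-based
# indices lives at data[(c - 1) * nrow + r].

#' @rdname elemType
#' @export
setMethod("elemType", "MatrixHandle", function(x) x@elemtype)

#' @rdname elemType
#' @export
setMethod("repType", "DenseMatrixHandle", function(x) "dense")
#' @rdname elemType
#' @export
setMethod("repType", "SparseMatrixHandle", function(x) "sparse_csc")
#' @rdname elemType
#' @export
setMethod("repType", "HDF5MatrixHandle", function(x) "hdf5")

newDenseHandle <- function(data, nrow, ncol, elemtype) {
    new("DenseMatrixHandle", nrow = as.integer(nrow), ncol = as.integer(ncol),
        elemtype = elemtype, data = data)
}

# infer the element type tag of an R vector/matrix
elemTypeOf <- function(v) {
    if (is.logical(v)) "logical"
    else if (is.integer(v)) "integer"
    else if (is.double(v)) "double"
    else if (is.character(v)) "string"
    else stop("unsupported element type: ", typeof(v))
}

denseFromRMatrix <- function(m) {
    et <- elemTypeOf(m)
    if (anyNA(m)) stop("missing values are not supported")
    newDenseHandle(as.vector(m), nrow(m), ncol(m), et)
}

#' @rdname accessors
#' @export
setMethod("getRow", "DenseMatrixHandle",
    function(x, r, first = 1L, last = NULL, counter = NULL) {
        r <- checkIndex(r, x@nrow, "row")
        ext <- checkExtent(first, last, x@ncol)
        if (ext[2] < ext[1]) return(x@data[0])
        x@data[(seq.int(ext[1], ext[2]) - 1L) * x@nrow + r]
    })

#' @rdname accessors
#' @export
setMethod("getCol", "DenseMatrixHandle",
    function(x, c, first = 1L, last = NULL, counter = NULL) {
        c <- checkIndex(c, x@ncol, "column")
        ext <- checkExtent(first, last, x@nrow)
        if (ext[2] < ext[1]) return(x@data[0])
        x@data[((c - 1L) * x@nrow + ext[1]):((c - 1L) * x@nrow + ext[2])]
    })

#' @rdname accessors
#' @export
setMethod("getElem", "DenseMatrixHandle",
    function(x, r, c, counter = NULL) {
        r <- checkIndex(r, x@nrow, "row")
        c <- checkIndex(c, x@ncol, "column")
        x@data[(c - 1L) * x@nrow + r]
    })

#' @rdname accessors
#' @export
setMethod("getColView", "DenseMatrixHandle", function(x, c) {
    c <- checkIndex(c, x@ncol, "column")
    v <- x@data[((c - 1L) * x@nrow + 1L):((c - 1L) * x@nrow + x@nrow)]
    if (x@nrow == 0L) v <- x@data[0]
    structure(list(values = v, nrow = x@nrow), class = "denseColumnView")
})

#' Materialise a column view
#'
#' Converts the read-only object returned by [getColView()] into a full
#' column vector, scattering stored nonzeros over zeros for sparse views.
#'
#' @param view a `denseColumnView` or `sparseColumnView`.
#' @param elemtype element type of the owning handle (used to type the
#'   zeros of a sparse scatter).
#' @return the column as a plain vector.
#' @export
materialiseView <- function(view, elemtype = "double") {
    if (inherits(view, "denseColumnView")) return(view$values)
    if (inherits(view, "sparseColumnView")) {
        out <- numeric(view$nrow)
        out[view$rows] <- view$values
        return(castToElem(out, elemtype))
    }
    stop("not a column view")
}

#' Materialise a handle as an ordinary R matrix
#'
#' Reads the full content of any backend into a dense R matrix; the
#' ground-truth oracle used throughout the package's tests.
#'
#' @param x a [MatrixHandle-class].
#' @param ... ignored.
#' @return a base R matrix of the handle's element type.
#' @export
setMethod("as.matrix", "DenseMatrixHandle", function(x, ...) {
    matrix(x@data, nrow = x@nrow, ncol = x@ncol)
})

#' @rdname as.matrix-DenseMatrixHandle-method
#' @export
setMethod("as.matrix", "SparseMatrixHandle", function(x, ...) {
    out <- matrix(0, nrow = x@nrow, ncol = x@ncol)
    if (length(x@x)) {
        cols <- rep.int(seq_len(x@ncol), diff(x@p))
        out[cbind(x@i + 1L, cols)] <- x@x
    }
    matrix(castToElem(as.vector(out), x@elemtype),
           nrow = x@nrow, ncol = x@ncol)
})

#' @rdname as.matrix-DenseMatrixHandle-method
#' @export
setMethod("as.matrix", "HDF5MatrixHandle", function(x, ...) {
    if (x@nrow == 0L || x@ncol == 0L) {
        blank <- switch(x@elemtype, integer = integer(0),
                        logical = logical(0), double = numeric(0),
                        string = character(0))
        return(matrix(blank, nrow = x@nrow, ncol = x@ncol))
    }
    v <- .cpp_h5_read_block(h5xp(x), 0L, x@nrow, 0L, x@ncol)
    matrix(v, nrow = x@nrow, ncol = x@ncol)
})
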