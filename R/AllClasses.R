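ELEM_TYPES <- c("integer", "logical", "double", "string")
REP_TYPES <- c("dense", "sparse_csc", "hdf5")

# element size in bytes as stored on disk / in cache accounting; strings use
# a nominal pointer-sized figure
elemBytes <- function(elemtype) {
    switch(elemtype, integer = 4L, logical = 4L, double = 8L, string = 8L,
           stop("unknown element type '", elemtype, "'"))
}

#' Virtual class for backend-agnostic matrix handles
#'
#' @description
#' A `MatrixHandle` is an opaque accessor over one concrete matrix
#' representation. Three subclasses exist:
#' \describe{
#'   \item{`DenseMatrixHandle`}{a contiguous column-major in-memory array.}
#'   \item{`SparseMatrixHandle`}{a compressed sparse column (CSC) store:
#'     nonzero values `x`, 0-based row indices `i`, and column offsets `p`
#'     of length `ncol + 1`, exactly the layout of `Matrix::dgCMatrix`.}
#'   \item{`HDF5MatrixHandle`}{a 2-D dataset in an HDF5 file, read in chunks
#'     through a package-managed, countable chunk cache; data are never
#'     fully materialised on opening.}
#' }
#' Handles are immutable after opening: repeated identical access requests
#' return identical values. Use [openMatrix()] to construct them and the
#' [accessors] to read from them.
#'
#' @slot nrow,ncol matrix dimensions.
#' @slot elemtype element type tag (`"integer"`, `"logical"`, `"double"`,
#'   `"string"`).
#'
#' @aliases MatrixHandle
#' @name MatrixHandle-class
#' @exportClass MatrixHandle
setClass("MatrixHandle", representation("VIRTUAL",
    nrow = "integer", ncol = "integer", elemtype = "character"))

setValidity("MatrixHandle", function(object) {
    if (length(object@nrow) != 1L || length(object@ncol) != 1L)
        return("nrow and ncol must be scalars")
    if (is.na(object@nrow) || is.na(object@ncol) ||
        object@nrow < 0L || object@ncol < 0L)
        return("dimensions must be nonnegative")
    if (!object@elemtype %in% ELEM_TYPES)
        return(paste0("unknown element type '", object@elemtype, "'"))
    TRUE
})

#' @rdname MatrixHandle-class
#' @slot data (dense) flat vector of length `nrow * ncol`, column-major.
#' @exportClass DenseMatrixHandle
setClass("DenseMatrixHandle", contains = "MatrixHandle",
    representation(data = "vector"))

setValidity("DenseMatrixHandle", function(object) {
    if (length(object@data) != as.double(object@nrow) * object@ncol)
        return("data length does not equal nrow * ncol")
    want <- switch(object@elemtype, integer = "integer", logical = "logical",
                   double = "double", string = "character")
    if (!identical(typeof(object@data), want))
        return(paste0("data storage mode does not match element type '",
                      object@elemtype, "'"))
    if (object@elemtype != "string" && anyNA(object@data))
        return("missing values are not supported")
    TRUE
})

#' @rdname MatrixHandle-class
#' @slot x (sparse) nonzero values in column-major order, stored as double.
#' @slot i (sparse) 0-based row indices aligned with `x`, strictly
#'   increasing within each column.
#' @slot p (sparse) column start offsets, length `ncol + 1`.
#' @slot cache (sparse) row-access cache state: per-column offsets `ptr` and
#'   the previously served row, advanced by [getRow()] to avoid redundant
#'   binary searches on consecutive or ordered row requests.
#' @exportClass SparseMatrixHandle
setClass("SparseMatrixHandle", contains = "MatrixHandle",
    representation(x = "numeric", i = "integer", p = "integer",
                   cache = "environment"))

setValidity("SparseMatrixHandle", function(object) {
    msg <- cscViolation(object@x, object@i, object@p,
                        object@nrow, object@ncol, object@elemtype)
    if (!is.null(msg)) return(msg)
    TRUE
})

#' @rdname MatrixHandle-class
#' @slot path,dataset (hdf5) file location and dataset name.
#' @slot layout (hdf5) chunk layout: list with `kind`
#'   (`"contiguous"`/`"chunked"`) and, if chunked, `chunkRows`, `chunkCols`.
#' @slot state (hdf5) open file handle, chunk cache and fetch counters.
#' @exportClass HDF5MatrixHandle
setClass("HDF5MatrixHandle", contains = "MatrixHandle",
    representation(path = "character", dataset = "character",
                   layout = "list", state = "environment"))

setMethod("dim", "MatrixHandle", function(x) c(x@nrow, x@ncol))

setMethod("show", "MatrixHandle", function(object) {
    cat(sprintf("<%s> %d x %d, element type %s\n",
                class(object), object@nrow, object@ncol, object@elemtype))
    if (is(object, "SparseMatrixHandle"))
        cat(sprintf("  %d stored values\n", length(object@x)))
    if (is(object, "HDF5MatrixHandle")) {
        lay <- object@layout
        cat(sprintf("  file: %s (dataset '%s'), layout %s%s\n",
                    object@path, object@dataset, lay$kind,
                    if (lay$kind == "chunked")
                        sprintf(" %d x %d", lay$chunkRows, lay$chunkCols)
                    else ""))
    }
    invisible(NULL)
})

# ---- shared internal helpers ----

# coerce a double working vector back to the handle's element type
castToElem <- function(v, elemtype) {
    switch(elemtype,
        integer = as.integer(v),
        logical = as.logical(v),
        double = v,
        string = as.character(v))
}

checkIndex <- function(idx, n, what) {
    if (length(idx) != 1L || is.na(idx) || idx < 1L || idx > n)
        stop(what, " index out of range (got ", idx, ", extent ", n, ")")
    as.integer(idx)
}

# resolve a closed 1-based extent [first, last] against dimension n;
# last = first - 1 denotes an empty extent
checkExtent <- function(first, last, n) {
    if (is.null(last)) last <- n
    first <- as.integer(first)
    last <- as.integer(last)
    if (is.na(first) || is.na(last) || first < 1L || last > n ||
        last < first - 1L)
        stop("invalid extent [", first, ", ", last, "] for dimension ", n)
    c(first, last)
}

countProbes <- function(counter, probes = 0, fetches = 0) {
    if (!is.null(counter)) {
        counter$indexComparisons <- counter$indexComparisons + probes
        counter$chunkFetches <- counter$chunkFetches + fetches
    }
    invisible(NULL)
}
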