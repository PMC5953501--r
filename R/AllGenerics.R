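#' @name accessors
#' @title Backend-agnostic matrix accessors
#'
#' @description
#' The accessor contract of the package: a `MatrixHandle` of any
#' representation answers row, column and single-entry requests with
#' identical values. `getRow()` and `getCol()` follow a copy-on-access
#' policy: the returned vector is a fresh copy that the caller may modify
#' without affecting the matrix. `getColView()` instead exposes a column
#' without copying (dense and sparse handles only); under R's value
#' semantics the view is read-only by construction.
#'
#' Indices are 1-based and extents are closed intervals `[first, last]`,
#' matching R conventions; `last = first - 1` denotes an empty extent.
#'
#' @param x a [MatrixHandle-class] object.
#' @param r,c 1-based row / column index.
#' @param first,last extent bounds within the vector being extracted
#'   (columns for `getRow()`, rows for `getCol()`). `last = NULL` means the
#'   full extent.
#' @param counter optional [newProbeCounter()] environment accumulating
#'   row-index comparisons and chunk fetches.
#'
#' @return `getRow()`/`getCol()` a vector of the handle's element type and
#'   length `last - first + 1`; `getElem()` a scalar; `getColView()` a
#'   `denseColumnView` (the column values) or `sparseColumnView` (a list
#'   with `values` and 1-based `rows` of the column's nonzeros).
#'
#' @examples
#' h <- openMatrix(matrix(c(1, 0, 2, 0, 0, 0, 0, 3, 4), nrow = 3))
#' getRow(h, 2)            # 0 0 3
#' getCol(h, 1)            # 1 0 2
#' getElem(h, 3, 3)        # 4
#' getRow(h, 3, first = 2, last = 3)   # 0 4
NULL

#' @rdname accessors
#' @export
setGeneric("getRow", function(x, r, first = 1L, last = NULL, counter = NULL)
    standardGeneric("getRow"))

#' @rdname accessors
#' @export
setGeneric("getCol", function(x, c, first = 1L, last = NULL, counter = NULL)
    standardGeneric("getCol"))

#' @rdname accessors
#' @export
setGeneric("getElem", function(x, r, c, counter = NULL)
    standardGeneric("getElem"))

#' @rdname accessors
#' @export
setGeneric("getColView", function(x, c) standardGeneric("getColView"))

#' Element type and representation of a handle
#'
#' @param x a [MatrixHandle-class].
#' @return `elemType()` one of `"integer"`, `"logical"`, `"double"`,
#'   `"string"`; `repType()` one of `"dense"`, `"sparse_csc"`, `"hdf5"`.
#' @examples
#' elemType(openMatrix(matrix(1:4, 2)))   # "integer"
#' repType(openMatrix(matrix(1:4, 2)))    # "dense"
#' @export
setGeneric("elemType", function(x) standardGeneric("elemType"))

#' @rdname elemType
#' @export
setGeneric("repType", function(x) standardGeneric("repType"))
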