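# Output builders: incremental writers that accumulate rows, columns or
# single entries and finalise to a handle of a chosen representation. The
# representation can be picked explicitly or matched to an input: results
# of processing come back in the representation the caller already chose
# for data of that size.

#' Output representation specification
#'
#' @description
#' Pairs a target representation with an element type (plus a chunk layout
#' for HDF5 targets). Sparse CSC output is only available for logical and
#' double elements, mirroring the sparse classes available at the R level
#' (`lgCMatrix` / `dgCMatrix`); there is no sparse integer or string
#' class, so those combinations are rejected.
#'
#' @param representation `"dense"`, `"sparse_csc"` or `"hdf5"`.
#' @param elemtype element type tag.
#' @param layout optional [chunkLayout()] for HDF5 targets.
#' @return a list with class `"outputSpec"`.
#' @export
outputSpec <- function(representation, elemtype, layout = NULL) {
    representation <- match.arg(representation, REP_TYPES)
    elemtype <- match.arg(elemtype, ELEM_TYPES)
    if (representation == "sparse_csc" &&
        !elemtype %in% c("logical", "double"))
        stop("unsupported sparse element type '", elemtype, "'")
    structure(list(representation = representation, elemtype = elemtype,
                   layout = layout), class = "outputSpec")
}

#' @export
print.outputSpec <- function(x, ...) {
    cat(sprintf("<outputSpec> %s, element type %s\n",
                x$representation, x$elemtype))
    invisible(x)
}

#' Match the output representation to an input representation
#'
#' @description
#' The automatic rule for choosing where results go: dense input implies
#' the caller can afford a dense result; HDF5 input implies the result is
#' similarly large and belongs on file; sparse input yields sparse output
#' where a sparse class exists for the element type (logical, double) and
#' falls back to dense otherwise (integer, string). The rule is total and
#' idempotent.
#'
#' @param inputRep representation of the input (`"dense"`, `"sparse_csc"`,
#'   `"hdf5"`).
#' @param elemtype element type of the output.
#' @param layout optional [chunkLayout()] carried into HDF5 specs.
#' @return an [outputSpec()].
#' @examples
#' matchOutputRepresentation("hdf5", "double")$representation    # "hdf5"
#' matchOutputRepresentation("sparse_csc", "integer")$representation # "dense"
#' @export
matchOutputRepresentation <- function(inputRep, elemtype, layout = NULL) {
    inputRep <- match.arg(inputRep, REP_TYPES)
    elemtype <- match.arg(elemtype, ELEM_TYPES)
    rep <- if (inputRep == "sparse_csc" &&
               !elemtype %in% c("logical", "double")) "dense"
           else inputRep
    outputSpec(rep, elemtype, layout = if (rep == "hdf5") layout)
}

#' Incremental matrix builders
#'
#' @description
#' `makeBuilder()` prepares an empty matrix of the spec's representation
#' (all entries zero, or the empty string); `builderSetCol()`,
#' `builderSetRow()` and `builderSetElem()` write into it, with
#' last-write-wins semantics on overlap; `finalizeBuilder()` closes the
#' builder and returns a handle. For sparse targets only nonzero values
#' are retained, so writing zeros never grows the store (but a zero
#' written over an earlier nonzero does erase it). A finalised builder
#' cannot be written to or finalised again.
#'
#' @param spec an [outputSpec()].
#' @param nrow,ncol dimensions of the matrix being built.
#' @param dest destination file for HDF5 targets (default: a tempfile).
#' @param dataset HDF5 dataset name.
#' @param b a builder.
#' @param idx 1-based row/column index being written.
#' @param r,c 1-based entry coordinates.
#' @param values vector of length `nrow` (`builderSetCol`) or `ncol`
#'   (`builderSetRow`); recycled scalars are not accepted.
#' @param value scalar for `builderSetElem`.
#' @return `makeBuilder()` a `matrixBuilder`; the setters the builder,
#'   invisibly; `finalizeBuilder()` a [MatrixHandle-class] that reads back
#'   exactly what was written.
#' @examples
#' b <- makeBuilder(outputSpec("sparse_csc", "double"), 3, 3)
#' builderSetCol(b, 1, c(1, 0, 2))
#' builderSetCol(b, 3, c(0, 3, 4))
#' h <- finalizeBuilder(b)
#' getRow(h, 3)   # 2 0 4
#' @export
makeBuilder <- function(spec, nrow, ncol, dest = NULL, dataset = "/matrix") {
    stopifnot(inherits(spec, "outputSpec"))
    if (spec$representation == "sparse_csc" &&
        !spec$elemtype %in% c("logical", "double"))
        stop("unsupported sparse element type '", spec$elemtype, "'")
    nrow <- as.integer(nrow); ncol <- as.integer(ncol)
    st <- new.env(parent = emptyenv())
    st$finalized <- FALSE
    if (spec$representation == "dense") {
        st$data <- if (spec$elemtype == "string")
            character(as.double(nrow) * ncol)
        else blankOf(spec$elemtype, as.double(nrow) * ncol)
    } else if (spec$representation == "sparse_csc") {
        # triplet journal; replayed last-write-wins at finalize
        st$ti <- integer(0)
        st$tj <- integer(0)
        st$tx <- numeric(0)
    } else {
        if (is.null(dest)) dest <- tempfile(fileext = ".h5")
        layout <- spec$layout
        if (is.null(layout)) layout <- chooseChunkDims(c(nrow, ncol), "mixed")
        if (layout$kind == "chunked" && (nrow > 0L && ncol > 0L))
            layout <- chunkLayout("chunked", min(layout$chunkRows, nrow),
                                  min(layout$chunkCols, ncol))
        createH5Dataset(dest, nrow, ncol, spec$elemtype, layout, dataset)
        st$dest <- dest
        st$dataset <- dataset
        st$wxp <- if (nrow > 0L && ncol > 0L)
            .cpp_h5_open(dest, dataset, FALSE) else NULL
    }
    structure(list(spec = spec, nrow = nrow, ncol = ncol, state = st),
              class = "matrixBuilder")
}

checkBuilderValues <- function(b, values, n) {
    if (length(values) != n)
        stop("expected ", n, " values, got ", length(values))
    if (anyNA(values)) stop("missing values are not supported")
    et <- b$spec$elemtype
    if (et == "string") {
        if (!is.character(values)) stop("type mismatch: expected strings")
        return(values)
    }
    if (!is.numeric(values) && !is.logical(values))
        stop("type mismatch: expected ", et, " values")
    if (et == "logical" && !all(values %in% c(0, 1)))
        stop("logical values must be 0 or 1")
    if (et == "integer" && any(values != trunc(values)))
        stop("type mismatch: non-integer values for integer element type")
    values
}

checkWritable <- function(b) {
    stopifnot(inherits(b, "matrixBuilder"))
    if (b$state$finalized) stop("builder already finalized")
}

#' @rdname makeBuilder
#' @export
builderSetCol <- function(b, idx, values) {
    checkWritable(b)
    idx <- checkIndex(idx, b$ncol, "column")
    values <- checkBuilderValues(b, values, b$nrow)
    st <- b$state
    rep <- b$spec$representation
    if (rep == "dense") {
        st$data[((idx - 1L) * b$nrow + 1L):((idx - 1L) * b$nrow + b$nrow)] <-
            castToElem(values, b$spec$elemtype)
    } else if (rep == "sparse_csc") {
        st$ti <- c(st$ti, seq_len(b$nrow))
        st$tj <- c(st$tj, rep.int(idx, b$nrow))
        st$tx <- c(st$tx, as.double(values))
    } else {
        .cpp_h5_write_block(st$wxp, 0L, b$nrow, idx - 1L, 1L,
                            castToElem(values, b$spec$elemtype))
    }
    invisible(b)
}

#' @rdname makeBuilder
#' @export
builderSetRow <- function(b, idx, values) {
    checkWritable(b)
    idx <- checkIndex(idx, b$nrow, "row")
    values <- checkBuilderValues(b, values, b$ncol)
    st <- b$state
    rep <- b$spec$representation
    if (rep == "dense") {
        st$data[(seq_len(b$ncol) - 1L) * b$nrow + idx] <-
            castToElem(values, b$spec$elemtype)
    } else if (rep == "sparse_csc") {
        st$ti <- c(st$ti, rep.int(idx, b$ncol))
        st$tj <- c(st$tj, seq_len(b$ncol))
        st$tx <- c(st$tx, as.double(values))
    } else {
        .cpp_h5_write_block(st$wxp, idx - 1L, 1L, 0L, b$ncol,
                            castToElem(values, b$spec$elemtype))
    }
    invisible(b)
}

#' @rdname makeBuilder
#' @export
builderSetElem <- function(b, r, c, value) {
    checkWritable(b)
    r <- checkIndex(r, b$nrow, "row")
    c <- checkIndex(c, b$ncol, "column")
    value <- checkBuilderValues(b, value, 1L)
    st <- b$state
    rep <- b$spec$representation
    if (rep == "dense") {
        st$data[(c - 1L) * b$nrow + r] <- castToElem(value, b$spec$elemtype)
    } else if (rep == "sparse_csc") {
        st$ti <- c(st$ti, r)
        st$tj <- c(st$tj, c)
        st$tx <- c(st$tx, as.double(value))
    } else {
        .cpp_h5_write_block(st$wxp, r - 1L, 1L, c - 1L, 1L,
                            castToElem(value, b$spec$elemtype))
    }
    invisible(b)
}

#' @rdname makeBuilder
#' @export
finalizeBuilder <- function(b) {
    checkWritable(b)
    st <- b$state
    st$finalized <- TRUE
    rep <- b$spec$representation
    if (rep == "dense") {
        return(newDenseHandle(st$data, b$nrow, b$ncol, b$spec$elemtype))
    }
    if (rep == "sparse_csc") {
        # last write wins: keep the final journal entry per coordinate,
        # then drop zeros and compact to CSC
        if (length(st$ti)) {
            keep <- !duplicated(cbind(st$ti, st$tj), fromLast = TRUE)
            i <- st$ti[keep]; j <- st$tj[keep]; x <- st$tx[keep]
        } else {
            i <- integer(0); j <- integer(0); x <- numeric(0)
        }
        return(sparseFromTriplets(i, j, x, b$nrow, b$ncol, b$spec$elemtype))
    }
    if (!is.null(st$wxp)) .cpp_h5_close(st$wxp)
    newHDF5Handle(st$dest, st$dataset)
}

#' @export
print.matrixBuilder <- function(x, ...) {
    cat(sprintf("<matrixBuilder> %s %s, %d x %d%s\n",
                x$spec$representation, x$spec$elemtype, x$nrow, x$ncol,
                if (x$state$finalized) " (finalized)" else ""))
    invisible(x)
}
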