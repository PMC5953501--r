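# Opening matrices from files and in-memory objects. The file extension
# chooses the representation: delimited text (dense), MatrixMarket
# coordinate files (sparse CSC), HDF5 (file-backed; the data are not
# materialised). In-memory sources keep their natural representation.

#' Open a matrix from a file or in-memory object
#'
#' @description
#' Constructs the appropriate [MatrixHandle-class] for a source:
#' \itemize{
#'   \item `.csv` / `.tsv` / `.txt`: a rectangular delimited grid of
#'     numbers or quoted strings (no header by default) -> dense handle.
#'   \item `.mtx`: MatrixMarket coordinate format (`real`, `integer` or
#'     `pattern`, `general` symmetry; 1-based on disk, converted to the
#'     package's internal 0-based CSC arrays) -> sparse handle. Duplicate
#'     or out-of-range coordinates are an error, never summed.
#'   \item `.h5` / `.hdf5`: one 2-D dataset (default `"/matrix"`) -> HDF5
#'     handle; only the geometry is read at open time.
#'   \item base `matrix`, `Matrix::dgCMatrix` / `lgCMatrix`: wrapped
#'     without conversion of representation.
#' }
#' Missing values in any source are rejected.
#'
#' @param source file path or in-memory matrix.
#' @param dataset HDF5 dataset name, default `"/matrix"`.
#' @param header whether delimited text has a header line (default FALSE).
#' @param cacheParams optional [chunkCacheParams()] for HDF5 sources.
#' @param ... passed to methods.
#' @return a [MatrixHandle-class] whose `repType()` reflects the source.
#' @examples
#' h <- openMatrix(matrix(c(1, 0, 2, 0, 0, 0, 0, 3, 4), nrow = 3))
#' repType(h)   # "dense"
#' s <- openMatrix(Matrix::Matrix(c(1, 0, 2, 0, 0, 0, 0, 3, 4), 3, 3,
#'                                sparse = TRUE))
#' repType(s)   # "sparse_csc"
#' @export
setGeneric("openMatrix", function(source, ...) standardGeneric("openMatrix"))

#' @rdname openMatrix
#' @export
setMethod("openMatrix", "character",
    function(source, dataset = "/matrix", header = FALSE,
             cacheParams = NULL, ...) {
        ext <- tolower(tools::file_ext(source))
        switch(ext,
            csv = readDelimMatrix(source, sep = ",", header = header),
            tsv = ,
            txt = readDelimMatrix(source, sep = "\t", header = header),
            mtx = readMTX(source),
            h5 = ,
            hdf5 = newHDF5Handle(source, dataset, params = cacheParams),
            stop("unrecognised matrix file extension '.", ext, "'"))
    })

#' @rdname openMatrix
#' @export
setMethod("openMatrix", "matrix", function(source, ...) {
    denseFromRMatrix(source)
})

#' @rdname openMatrix
#' @export
setMethod("openMatrix", "CsparseMatrix", function(source, ...) {
    et <- if (is(source, "lMatrix") || is(source, "nMatrix")) "logical"
          else "double"
    x <- if (is(source, "nMatrix")) rep(1, length(source@i)) else source@x
    if (anyNA(x)) stop("missing values are not supported")
    newSparseHandle(as.double(x), source@i, source@p,
                    nrow(source), ncol(source), et)
})

readDelimMatrix <- function(path, sep, header) {
    if (!file.exists(path)) stop("cannot open file '", path, "'")
    df <- utils::read.table(path, sep = sep, header = header,
                            stringsAsFactors = FALSE, colClasses = NA,
                            check.names = FALSE)
    cls <- vapply(df, function(col) class(col)[1], character(1))
    et <- if (any(cls == "character")) "string"
          else if (all(cls == "logical") && nrow(df) > 0) "logical"
          else if (all(cls == "integer")) "integer"
          else "double"
    m <- switch(et,
        string = as.matrix(as.data.frame(lapply(df, as.character),
                                         check.names = FALSE)),
        logical = as.matrix(as.data.frame(lapply(df, as.logical),
                                          check.names = FALSE)),
        integer = as.matrix(as.data.frame(lapply(df, as.integer),
                                          check.names = FALSE)),
        as.matrix(as.data.frame(lapply(df, as.double),
                                check.names = FALSE)))
    dimnames(m) <- NULL
    if (anyNA(m)) stop("missing values are not supported in '", path, "'")
    newDenseHandle(as.vector(m), nrow(m), ncol(m), et)
}

# field entry of the MatrixMarket banner: real | integer | pattern
mtxField <- function(path) {
    banner <- readLines(path, n = 1L)
    parts <- strsplit(trimws(banner), "[[:space:]]+")[[1]]
    if (length(parts) < 5L || !identical(parts[1], "%%MatrixMarket") ||
        parts[2] != "matrix" || parts[3] != "coordinate")
        stop("'", path, "' is not a MatrixMarket coordinate file")
    if (parts[5] != "general")
        stop("only 'general' MatrixMarket symmetry is supported")
    field <- parts[4]
    if (!field %in% c("real", "integer", "pattern"))
        stop("unsupported MatrixMarket field '", field, "'")
    field
}

readMTX <- function(path) {
    if (!file.exists(path)) stop("cannot open file '", path, "'")
    field <- mtxField(path)
    tm <- Matrix::readMM(path)      # triplet form keeps duplicates visible
    i <- tm@i + 1L
    j <- tm@j + 1L
    if (anyDuplicated(cbind(i, j)))
        stop("duplicate coordinates in '", path, "'")
    x <- if (field == "pattern") rep(1, length(i)) else tm@x
    if (anyNA(x)) stop("missing values are not supported in '", path, "'")
    et <- switch(field, real = "double", integer = "integer",
                 pattern = "logical")
    if (et == "integer" && any(x != trunc(x)))
        stop("non-integer values in integer MatrixMarket file")
    sparseFromTriplets(i, j, as.double(x), nrow(tm), ncol(tm), et)
}

# ---- writers ----

#' Write a matrix handle to a file
#'
#' Writes any handle to `.csv`/`.tsv` (dense grid), `.mtx` (MatrixMarket
#' coordinate, entries in column-major order, `integer`/`real`/`pattern`
#' field chosen from the element type) or `.h5` (2-D dataset with an
#' `element_type` attribute). Values round-trip exactly through
#' [openMatrix()].
#'
#' @param h a [MatrixHandle-class].
#' @param path destination; the extension picks the format.
#' @param dataset HDF5 dataset name, default `"/matrix"`.
#' @param layout optional [chunkLayout()] for HDF5 output.
#' @return the path, invisibly.
#' @export
writeMatrix <- function(h, path, dataset = "/matrix", layout = NULL) {
    stopifnot(is(h, "MatrixHandle"))
    ext <- tolower(tools::file_ext(path))
    switch(ext,
        csv = writeDelim(h, path, ","),
        tsv = ,
        txt = writeDelim(h, path, "\t"),
        mtx = writeMTX(h, path),
        h5 = ,
        hdf5 = writeH5(h, path, dataset, layout),
        stop("unrecognised matrix file extension '.", ext, "'"))
    invisible(path)
}

writeDelim <- function(h, path, sep) {
    m <- as.matrix(h)
    if (elemType(h) == "double") {
        # full precision, and keep a decimal point so whole values read
        # back as doubles rather than integers
        v <- sprintf("%.17g", m)
        plain <- !grepl("[.eE]", v)
        v[plain] <- paste0(v[plain], ".0")
        m <- matrix(v, nrow = nrow(m))
    }
    utils::write.table(m, path, sep = sep, row.names = FALSE,
                       col.names = FALSE, quote = elemType(h) == "string")
}

fmtMTXValue <- function(x, field) {
    if (field == "integer") sprintf("%d", as.integer(x))
    else sprintf("%.17g", x)
}

writeMTX <- function(h, path) {
    et <- elemType(h)
    if (et == "string") stop("sparse strings unsupported")
    s <- if (is(h, "SparseMatrixHandle")) h else cscFromDense(as.matrix(h))
    field <- switch(et, logical = "pattern", integer = "integer",
                    double = "real")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%%%%MatrixMarket matrix coordinate %s general",
                       field), con)
    writeLines(sprintf("%d %d %d", s@nrow, s@ncol, length(s@x)), con)
    if (length(s@x)) {
        cols <- rep.int(seq_len(s@ncol), diff(s@p))   # column-major order
        lines <- if (field == "pattern")
            sprintf("%d %d", s@i + 1L, cols)
        else sprintf("%d %d %s", s@i + 1L, cols, fmtMTXValue(s@x, field))
        writeLines(lines, con)
    }
}

writeH5 <- function(h, path, dataset, layout) {
    if (is.null(layout))
        layout <- chooseChunkDims(dim(h), "mixed")
    createH5Dataset(path, nrow(h), ncol(h), elemType(h),
                    layout = layout, dataset = dataset)
    if (nrow(h) > 0L && ncol(h) > 0L) {
        wxp <- .cpp_h5_open(path, dataset, FALSE)
        m <- as.matrix(h)
        .cpp_h5_write_block(wxp, 0L, nrow(h), 0L, ncol(h), as.vector(m))
        .cpp_h5_close(wxp)
    }
    invisible(newHDF5Handle(path, dataset))
}
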