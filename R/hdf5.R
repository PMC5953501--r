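# HDF5-backed matrices. The file is the store: opening a handle reads only
# the dataset's geometry, and data reach memory chunk by chunk through a
# package-managed cache. The cache is maintained here (keyed by chunk
# coordinates, LRU eviction under a byte budget) rather than delegating to
# the HDF5 library's internal cache, so that chunk fetches are countable
# and the tuned-cache guarantee -- one fetch per chunk during a full
# consecutive sweep -- is assertable.

ACCESS_PATTERNS <- c("consecutive_rows", "consecutive_cols",
                     "random_rows", "random_cols", "mixed")

#' Chunk layouts for HDF5 datasets
#'
#' @description
#' `chunkLayout()` describes how a 2-D HDF5 dataset is tiled on disk:
#' either one contiguous block, or rectangular chunks of `chunkRows` x
#' `chunkCols` elements, the atomic unit of file I/O.
#'
#' @param kind `"contiguous"` or `"chunked"`.
#' @param chunkRows,chunkCols chunk dimensions (chunked layouts only).
#' @return a list with class `"chunkLayout"`.
#' @examples
#' chunkLayout("chunked", 40, 40)
#' @export
chunkLayout <- function(kind = c("chunked", "contiguous"),
                        chunkRows = NULL, chunkCols = NULL) {
    kind <- match.arg(kind)
    if (kind == "contiguous")
        return(structure(list(kind = "contiguous"), class = "chunkLayout"))
    chunkRows <- as.integer(chunkRows)
    chunkCols <- as.integer(chunkCols)
    if (is.na(chunkRows) || is.na(chunkCols) || chunkRows < 1L || chunkCols < 1L)
        stop("chunk dimensions must be positive integers")
    structure(list(kind = "chunked", chunkRows = chunkRows,
                   chunkCols = chunkCols), class = "chunkLayout")
}

#' @export
print.chunkLayout <- function(x, ...) {
    if (x$kind == "contiguous") cat("<chunkLayout> contiguous\n")
    else cat(sprintf("<chunkLayout> chunked %d x %d\n",
                     x$chunkRows, x$chunkCols))
    invisible(x)
}

#' Chunk-cache parameters
#'
#' @description
#' The in-memory chunk cache of an HDF5-backed handle is controlled by the
#' number of slots (`nslots`, kept prime so chunk coordinates hash without
#' collisions in the classic HDF5 scheme), a byte capacity (`nbytes`), and
#' a preemption weight `w0` in \[0, 1\] (1 favours evicting fully-read
#' chunks first; recorded for fidelity with the HDF5 parameterisation,
#' eviction here is LRU).
#'
#' @param nslots positive slot count.
#' @param nbytes cache capacity in bytes.
#' @param w0 preemption weight in \[0, 1\].
#' @return a list with class `"chunkCacheParams"`.
#' @seealso [tuneChunkCache()] for the automatic policy.
#' @export
chunkCacheParams <- function(nslots = 521L, nbytes = 1048576,
                             w0 = 0.75) {
    nslots <- as.integer(nslots)
    if (is.na(nslots) || nslots < 1L) stop("nslots must be >= 1")
    if (!is.finite(nbytes) || nbytes < 0) stop("nbytes must be nonnegative")
    if (!is.finite(w0) || w0 < 0 || w0 > 1) stop("w0 must be in [0, 1]")
    structure(list(nslots = nslots, nbytes = as.double(nbytes), w0 = w0),
              class = "chunkCacheParams")
}

#' @export
print.chunkCacheParams <- function(x, ...) {
    cat(sprintf("<chunkCacheParams> nslots = %d, nbytes = %.0f, w0 = %.2f\n",
                x$nslots, x$nbytes, x$w0))
    invisible(x)
}

# ---- handle construction ----

# the open C-level handle, opened lazily and cached in the state env
h5xp <- function(h) {
    st <- h@state
    if (is.null(st$xp)) st$xp <- .cpp_h5_open(h@path, h@dataset, TRUE)
    st$xp
}

resetChunkCacheStore <- function(st) {
    st$chunks <- list()
    st$lru <- character(0)
    st$bytes <- 0
}

newHDF5Handle <- function(path, dataset, params = NULL) {
    xp <- .cpp_h5_open(path, dataset, TRUE)
    info <- .cpp_h5_info(xp)
    layout <- if (info$chunked)
        chunkLayout("chunked", info$chunk_rows, info$chunk_cols)
    else chunkLayout("contiguous")
    if (!info$elemtype %in% ELEM_TYPES)
        stop("unsupported element type '", info$elemtype, "'")
    st <- new.env(parent = emptyenv())
    st$xp <- xp
    chunkBytes <- if (info$chunked)
        info$chunk_rows * info$chunk_cols * elemBytes(info$elemtype)
    else 0
    st$chunkBytes <- chunkBytes
    if (is.null(params)) params <- chunkCacheParams()
    st$params <- params
    resetChunkCacheStore(st)
    new("HDF5MatrixHandle", nrow = as.integer(info$nrow),
        ncol = as.integer(info$ncol), elemtype = info$elemtype,
        path = path, dataset = dataset, layout = unclass(layout), state = st)
}

#' Create a zero-filled HDF5-backed matrix
#'
#' Creates a 2-D dataset with the requested chunk geometry (or contiguous
#' layout), records the element type in a string attribute
#' `"element_type"` on the dataset, and returns a handle. All entries read
#' as zero (empty string for string matrices) until written.
#'
#' @param path file to create (or extend, if it already holds other
#'   datasets).
#' @param nrow,ncol matrix dimensions.
#' @param elemtype element type tag.
#' @param layout a [chunkLayout()]; defaults to the square layout chosen by
#'   [chooseChunkDims()] for mixed access.
#' @param dataset dataset name, default `"/matrix"`.
#' @param compress gzip level 0-9; 0 (default) writes uncompressed.
#' @return an [MatrixHandle-class] with representation `"hdf5"`.
#' @examples
#' f <- tempfile(fileext = ".h5")
#' h <- createHDF5Matrix(f, 10, 10, "double",
#'                       layout = chunkLayout("chunked", 5, 5))
#' getElem(h, 1, 1)   # 0
#' @export
createHDF5Matrix <- function(path, nrow, ncol, elemtype = "double",
                             layout = NULL, dataset = "/matrix",
                             compress = 0L) {
    createH5Dataset(path, nrow, ncol, elemtype, layout, dataset, compress)
    newHDF5Handle(path, dataset)
}

# create the dataset without opening a handle on it (writers need the file
# unclaimed: HDF5 refuses mixed read-only/read-write opens of one file)
createH5Dataset <- function(path, nrow, ncol, elemtype, layout, dataset,
                            compress = 0L) {
    if (!elemtype %in% ELEM_TYPES)
        stop("unsupported element type '", elemtype, "'")
    nrow <- as.integer(nrow); ncol <- as.integer(ncol)
    if (is.null(layout)) layout <- chooseChunkDims(c(nrow, ncol), "mixed")
    chunked <- layout$kind == "chunked"
    .cpp_h5_create(path, dataset, nrow, ncol, elemtype, chunked,
                   if (chunked) layout$chunkRows else 0L,
                   if (chunked) layout$chunkCols else 0L,
                   as.integer(compress))
    invisible(path)
}

#' Chunk layout of an HDF5 handle
#'
#' @param h an `HDF5MatrixHandle`.
#' @return the dataset's [chunkLayout()].
#' @export
h5Layout <- function(h) {
    stopifnot(is(h, "HDF5MatrixHandle"))
    structure(h@layout, class = "chunkLayout")
}

#' Get or set the chunk-cache parameters of an HDF5 handle
#'
#' @param h an `HDF5MatrixHandle`.
#' @param params a [chunkCacheParams()] (for instance from
#'   [tuneChunkCache()]). Setting new parameters empties the cache.
#' @return `getChunkCache()` the current parameters; `setChunkCache()` the
#'   handle, invisibly.
#' @export
setChunkCache <- function(h, params) {
    stopifnot(is(h, "HDF5MatrixHandle"), inherits(params, "chunkCacheParams"))
    h@state$params <- params
    resetChunkCacheStore(h@state)
    invisible(h)
}

#' @rdname setChunkCache
#' @export
getChunkCache <- function(h) {
    stopifnot(is(h, "HDF5MatrixHandle"))
    h@state$params
}

# ---- layout selection and cache tuning ----

#' Choose chunk dimensions for an expected access pattern
#'
#' @description
#' Picks a chunk geometry at file-creation time from the access pattern
#' expected downstream. Sequential (and mixed) access favours square
#' chunks, which serve consecutive row and column sweeps equally well once
#' the cache holds a full stripe; the side is capped at 100 and at the
#' matrix dimensions. Random single-row access favours chunks that span
#' one row (up to 5000 values), so each fetch reads only requested data;
#' symmetrically for random column access.
#'
#' @param shape integer vector `c(nrow, ncol)`.
#' @param pattern one of `"consecutive_rows"`, `"consecutive_cols"`,
#'   `"random_rows"`, `"random_cols"`, `"mixed"`.
#' @return a [chunkLayout()]; contiguous for zero-extent matrices.
#' @examples
#' chooseChunkDims(c(10000, 8000), "random_rows")   # 1 x 5000 chunks
#' chooseChunkDims(c(50, 2000), "mixed")            # 50 x 100 chunks
#' @export
chooseChunkDims <- function(shape, pattern = "mixed") {
    pattern <- match.arg(pattern, ACCESS_PATTERNS)
    nrow <- as.integer(shape[1]); ncol <- as.integer(shape[2])
    if (nrow == 0L || ncol == 0L) return(chunkLayout("contiguous"))
    switch(pattern,
        random_rows = chunkLayout("chunked", 1L, min(ncol, 5000L)),
        random_cols = chunkLayout("chunked", min(nrow, 5000L), 1L),
        chunkLayout("chunked", min(nrow, 100L), min(ncol, 100L)))
}

smallestPrimeAtLeast <- function(n) {
    n <- max(as.integer(n), 2L)
    isPrime <- function(k) {
        if (k < 4L) return(k >= 2L)
        if (k %% 2L == 0L) return(FALSE)
        d <- 3L
        while (d * d <= k) {
            if (k %% d == 0L) return(FALSE)
            d <- d + 2L
        }
        TRUE
    }
    while (!isPrime(n)) n <- n + 1L
    n
}

#' Tune the chunk cache for a sweep pattern
#'
#' @description
#' Sizes the chunk cache so that a full consecutive sweep fetches each
#' chunk from file exactly once. For consecutive row access the working
#' set is one horizontal stripe of chunks: `nChunks = ceiling(ncol /
#' chunkCols)` chunks of `chunkRows * chunkCols * elemBytes` bytes each;
#' `nbytes` is set to exactly that stripe, `nslots` to the smallest prime
#' at least `100 * nChunks`, and the preemption weight `w0` to 1 for
#' consecutive patterns (fully-read chunks are never needed again within a
#' stripe) and 0.75 otherwise. Consecutive column access is symmetric with
#' vertical stripes; random and mixed patterns are sized for the larger of
#' the two stripes.
#'
#' @param layout a chunked [chunkLayout()] (contiguous layouts have no
#'   cache to tune).
#' @param shape integer vector `c(nrow, ncol)`.
#' @param elemtype element type tag (determines bytes per element).
#' @param pattern expected access pattern, as in [chooseChunkDims()].
#' @return a [chunkCacheParams()].
#' @examples
#' tuneChunkCache(chunkLayout("chunked", 40, 40), c(10000, 1000),
#'                "double", "consecutive_rows")
#' # nbytes = 25 * 40 * 40 * 8 = 320000, nslots = 2503, w0 = 1
#' @export
tuneChunkCache <- function(layout, shape, elemtype = "double",
                           pattern = "consecutive_rows") {
    pattern <- match.arg(pattern, ACCESS_PATTERNS)
    if (layout$kind != "chunked") stop("no cache to tune")
    nrow <- as.double(shape[1]); ncol <- as.double(shape[2])
    eb <- elemBytes(elemtype)
    chunkB <- layout$chunkRows * layout$chunkCols * eb
    rowStripe <- ceiling(ncol / layout$chunkCols)
    colStripe <- ceiling(nrow / layout$chunkRows)
    nChunks <- switch(pattern,
        consecutive_rows = rowStripe,
        random_rows = rowStripe,
        consecutive_cols = colStripe,
        random_cols = colStripe,
        mixed = max(rowStripe, colStripe))
    nChunks <- max(nChunks, 1)
    w0 <- if (pattern %in% c("consecutive_rows", "consecutive_cols")) 1.0
          else 0.75
    chunkCacheParams(nslots = smallestPrimeAtLeast(100 * nChunks),
                     nbytes = nChunks * chunkB, w0 = w0)
}

# ---- chunked access through the cache ----

# fetch one chunk (0-based chunk coordinates), as a typed R matrix clipped
# at the dataset edge; counts a fetch only on cache miss
fetchChunk <- function(h, cr, cc, counter = NULL) {
    st <- h@state
    key <- paste0(cr, "_", cc)
    blk <- st$chunks[[key]]
    if (!is.null(blk)) {
        if (st$lru[length(st$lru)] != key) {
            st$lru <- c(st$lru[st$lru != key], key)
        }
        return(blk)
    }
    lay <- h@layout
    row0 <- cr * lay$chunkRows
    col0 <- cc * lay$chunkCols
    nr <- min(lay$chunkRows, h@nrow - row0)
    nc <- min(lay$chunkCols, h@ncol - col0)
    v <- .cpp_h5_read_block(h5xp(h), row0, nr, col0, nc)
    blk <- matrix(v, nrow = nr, ncol = nc)
    countProbes(counter, fetches = 1)
    p <- st$params
    if (st$chunkBytes <= p$nbytes) {
        while ((st$bytes + st$chunkBytes > p$nbytes ||
                length(st$lru) >= p$nslots) && length(st$lru)) {
            drop <- st$lru[1L]
            st$lru <- st$lru[-1L]
            st$chunks[[drop]] <- NULL
            st$bytes <- st$bytes - st$chunkBytes
        }
        st$chunks[[key]] <- blk
        st$lru <- c(st$lru, key)
        st$bytes <- st$bytes + st$chunkBytes
    }
    blk
}

blankOf <- function(elemtype, n) {
    vector(switch(elemtype, integer = "integer", logical = "logical",
                  double = "numeric", string = "character"), n)
}

#' @rdname accessors
#' @export
setMethod("getRow", "HDF5MatrixHandle",
    function(x, r, first = 1L, last = NULL, counter = NULL) {
        r <- checkIndex(r, x@nrow, "row")
        ext <- checkExtent(first, last, x@ncol)
        n <- ext[2] - ext[1] + 1L
        if (n <= 0L) return(blankOf(x@elemtype, 0L))
        if (x@layout$kind != "chunked") {
            countProbes(counter, fetches = 1)
            return(.cpp_h5_read_block(h5xp(x), r - 1L, 1L, ext[1] - 1L, n))
        }
        ck <- x@layout$chunkCols
        cr <- (r - 1L) %/% x@layout$chunkRows
        out <- blankOf(x@elemtype, n)
        localRow <- r - cr * x@layout$chunkRows
        for (cc in ((ext[1] - 1L) %/% ck):((ext[2] - 1L) %/% ck)) {
            blk <- fetchChunk(x, cr, cc, counter)
            c0 <- cc * ck + 1L                       # first matrix col in chunk
            a <- max(ext[1], c0)
            b <- min(ext[2], c0 + ncol(blk) - 1L)
            out[(a - ext[1] + 1L):(b - ext[1] + 1L)] <-
                blk[localRow, (a - c0 + 1L):(b - c0 + 1L)]
        }
        out
    })

#' @rdname accessors
#' @export
setMethod("getCol", "HDF5MatrixHandle",
    function(x, c, first = 1L, last = NULL, counter = NULL) {
        c <- checkIndex(c, x@ncol, "column")
        ext <- checkExtent(first, last, x@nrow)
        n <- ext[2] - ext[1] + 1L
        if (n <= 0L) return(blankOf(x@elemtype, 0L))
        if (x@layout$kind != "chunked") {
            countProbes(counter, fetches = 1)
            return(.cpp_h5_read_block(h5xp(x), ext[1] - 1L, n, c - 1L, 1L))
        }
        rk <- x@layout$chunkRows
        cc <- (c - 1L) %/% x@layout$chunkCols
        out <- blankOf(x@elemtype, n)
        localCol <- c - cc * x@layout$chunkCols
        for (cr in ((ext[1] - 1L) %/% rk):((ext[2] - 1L) %/% rk)) {
            blk <- fetchChunk(x, cr, cc, counter)
            r0 <- cr * rk + 1L
            a <- max(ext[1], r0)
            b <- min(ext[2], r0 + nrow(blk) - 1L)
            out[(a - ext[1] + 1L):(b - ext[1] + 1L)] <-
                blk[(a - r0 + 1L):(b - r0 + 1L), localCol]
        }
        out
    })

#' @rdname accessors
#' @export
setMethod("getElem", "HDF5MatrixHandle",
    function(x, r, c, counter = NULL) {
        r <- checkIndex(r, x@nrow, "row")
        c <- checkIndex(c, x@ncol, "column")
        if (x@layout$kind != "chunked") {
            countProbes(counter, fetches = 1)
            return(.cpp_h5_read_block(h5xp(x), r - 1L, 1L, c - 1L, 1L))
        }
        cr <- (r - 1L) %/% x@layout$chunkRows
        cc <- (c - 1L) %/% x@layout$chunkCols
        blk <- fetchChunk(x, cr, cc, counter)
        blk[r - cr * x@layout$chunkRows, c - cc * x@layout$chunkCols]
    })

# ---- layout conversion ----

#' Convert an HDF5-backed matrix to a new chunk layout
#'
#' @description
#' Streams an HDF5 dataset into a new file with a different chunk layout,
#' stripe by stripe, never materialising the whole matrix: the working
#' buffer is at most `budgetBytes`. Values, positions and the element-type
#' attribute are preserved exactly; requested chunk dimensions larger than
#' the matrix are capped at the matrix dimensions. Converting a
#' column-friendly layout (e.g. `1 x 5000` chunks) to a row-friendly one
#' (`5000 x 1`) and back is a bitwise identity on the values.
#'
#' @param src an `HDF5MatrixHandle` or a path to an HDF5 file.
#' @param destPath file to create.
#' @param layout target [chunkLayout()].
#' @param budgetBytes working-memory budget in bytes; must cover one source
#'   chunk-row stripe plus one destination chunk-row stripe.
#' @param dataset dataset name in source and destination (default: the
#'   source handle's, or `"/matrix"`).
#' @param compress gzip level for the destination, default 0.
#' @return handle on the converted matrix, with attribute
#'   `"peakBufferBytes"` recording the planner's peak buffer allocation.
#' @export
rechunk <- function(src, destPath, layout, budgetBytes = 64 * 1024^2,
                    dataset = NULL, compress = 0L) {
    if (is.character(src))
        src <- newHDF5Handle(src, if (is.null(dataset)) "/matrix" else dataset)
    stopifnot(is(src, "HDF5MatrixHandle"))
    if (is.null(dataset)) dataset <- src@dataset
    nrow <- src@nrow; ncol <- src@ncol
    eb <- elemBytes(src@elemtype)

    if (layout$kind == "chunked") {
        layout <- chunkLayout("chunked",
                              min(layout$chunkRows, max(nrow, 1L)),
                              min(layout$chunkCols, max(ncol, 1L)))
    }
    srcRows <- if (src@layout$kind == "chunked") src@layout$chunkRows else 1L
    destRows <- if (layout$kind == "chunked") layout$chunkRows else 1L
    need <- (as.double(srcRows) + destRows) * ncol * eb
    if (nrow > 0L && ncol > 0L && budgetBytes < need)
        stop(sprintf(
            "budget of %.0f bytes is below one source + one destination stripe (%.0f bytes)",
            budgetBytes, need))

    createH5Dataset(destPath, nrow, ncol, src@elemtype,
                    layout = layout, dataset = dataset, compress = compress)
    peak <- 0
    if (nrow > 0L && ncol > 0L) {
        # block height: fits twice (read buffer + transpose copy) in budget,
        # aligned to destination chunk rows where possible
        H <- max(1, floor(budgetBytes / (2 * as.double(ncol) * eb)))
        if (H >= destRows) H <- (H %/% destRows) * destRows
        H <- min(H, nrow)
        wxp <- .cpp_h5_open(destPath, dataset, FALSE)
        r0 <- 0L
        while (r0 < nrow) {
            h <- min(H, nrow - r0)
            v <- .cpp_h5_read_block(h5xp(src), r0, h, 0L, ncol)
            .cpp_h5_write_block(wxp, r0, h, 0L, ncol, v)
            peak <- max(peak, 2 * as.double(h) * ncol * eb)
            r0 <- r0 + h
        }
        .cpp_h5_close(wxp)
    }
    out <- newHDF5Handle(destPath, dataset)
    attr(out, "peakBufferBytes") <- peak
    out
}
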