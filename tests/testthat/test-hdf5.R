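test_that("creation honours the requested chunk geometry and zero-fills", {
    f <- tempfile(fileext = ".h5")
    h <- createHDF5Matrix(f, 1000, 100, "double",
                          layout = chunkLayout("chunked", 40, 40))
    lay <- h5Layout(h)
    expect_identical(lay$kind, "chunked")
    expect_identical(c(lay$chunkRows, lay$chunkCols), c(40L, 40L))
    expect_identical(getElem(h, 1, 1), 0)
    expect_equal(as.vector(getRow(h, 500)), rep(0, 100))

    expect_error(createHDF5Matrix(tempfile(fileext = ".h5"), 10, 10, "double",
                                  layout = chunkLayout("chunked", 20, 20)),
                 "exceed")
    expect_error(createHDF5Matrix(file.path(tempfile(), "no", "way.h5"),
                                  5, 5, "double"))
})

test_that("the element_type attribute survives the round trip for every type", {
    for (et in c("integer", "logical", "double", "string")) {
        m <- randomDense(9, 4, et, 1, seed = 77)
        h <- asTempH5(openMatrix(m))
        expect_identical(elemType(h), et)
        expect_identical(unname(as.matrix(h)), m)
    }
})

test_that("chunk dimensions follow the access-pattern policy", {
    expect_equal(unclass(chooseChunkDims(c(10000, 8000), "random_rows")),
                 list(kind = "chunked", chunkRows = 1L, chunkCols = 5000L))
    expect_equal(unclass(chooseChunkDims(c(10000, 8000), "random_cols")),
                 list(kind = "chunked", chunkRows = 5000L, chunkCols = 1L))
    expect_equal(unclass(chooseChunkDims(c(10000, 1000), "mixed")),
                 list(kind = "chunked", chunkRows = 100L, chunkCols = 100L))
    expect_equal(unclass(chooseChunkDims(c(50, 2000), "mixed")),
                 list(kind = "chunked", chunkRows = 50L, chunkCols = 100L))
    expect_identical(chooseChunkDims(c(0, 10), "mixed")$kind, "contiguous")
})

test_that("cache tuning sizes one stripe, prime slots, and full preemption for sweeps", {
    p <- tuneChunkCache(chunkLayout("chunked", 40, 40), c(10000, 1000),
                        "double", "consecutive_rows")
    expect_identical(p$nbytes, 25 * 40 * 40 * 8)   # one horizontal stripe
    expect_identical(p$nslots, 2503L)              # smallest prime >= 2500
    expect_identical(p$w0, 1.0)

    p1 <- tuneChunkCache(chunkLayout("chunked", 1, 600), c(50, 600),
                         "double", "consecutive_rows")
    expect_identical(p1$nbytes, 1 * 600 * 8)       # single chunk per stripe

    pc <- tuneChunkCache(chunkLayout("chunked", 40, 40), c(10000, 1000),
                         "double", "consecutive_cols")
    expect_identical(pc$nbytes, 250 * 40 * 40 * 8)
    pr <- tuneChunkCache(chunkLayout("chunked", 40, 40), c(10000, 1000),
                         "double", "random_rows")
    expect_identical(pr$w0, 0.75)

    expect_error(tuneChunkCache(chunkLayout("contiguous"), c(10, 10)),
                 "no cache to tune")
})

test_that("a tuned consecutive sweep fetches each chunk exactly once", {
    m <- randomDense(200, 120, "double", 1, seed = 5)
    h <- asTempH5(openMatrix(m), layout = chunkLayout("chunked", 25, 30))
    setChunkCache(h, tuneChunkCache(h5Layout(h), dim(h), "double",
                                    "consecutive_rows"))
    pc <- newProbeCounter()
    for (r in seq_len(200))
        expect_equal(as.vector(getRow(h, r, counter = pc)), unname(m[r, ]))
    expect_identical(probeReport(pc)$chunkFetches, 8 * 4)  # chunk grid

    # column sweep under column tuning
    setChunkCache(h, tuneChunkCache(h5Layout(h), dim(h), "double",
                                    "consecutive_cols"))
    pc2 <- newProbeCounter()
    for (cc in seq_len(120))
        expect_equal(as.vector(getCol(h, cc, counter = pc2)), unname(m[, cc]))
    expect_identical(probeReport(pc2)$chunkFetches, 8 * 4)
})

test_that("an undersized cache refetches a chunk stripe on every row", {
    m <- randomDense(100, 120, "double", 1, seed = 6)
    h <- asTempH5(openMatrix(m), layout = chunkLayout("chunked", 25, 30))
    setChunkCache(h, chunkCacheParams(nslots = 1,
                                      nbytes = 25 * 30 * 8, w0 = 1))
    pc <- newProbeCounter()
    for (r in seq_len(100)) getRow(h, r, counter = pc)
    expect_gte(probeReport(pc)$chunkFetches, 4 * 100)
})

test_that("contiguous layouts read correctly without a chunk cache", {
    m <- randomDense(30, 12, "double", 1, seed = 8)
    h <- asTempH5(openMatrix(m), layout = chunkLayout("contiguous"))
    expect_identical(h5Layout(h)$kind, "contiguous")
    expect_equal(as.vector(getRow(h, 17)), unname(m[17, ]))
    expect_equal(as.vector(getCol(h, 12, first = 5, last = 20)),
                 unname(m[5:20, 12]))
})

test_that("rechunk preserves values bitwise, caps chunk dims and respects its budget", {
    m <- randomDense(80, 50, "double", 1, seed = 12)
    src <- asTempH5(openMatrix(m), layout = chunkLayout("chunked", 1, 50))
    f1 <- tempfile(fileext = ".h5")
    a <- rechunk(src, f1, chunkLayout("chunked", 5000, 1),
                 budgetBytes = 2^20)
    expect_identical(h5Layout(a)$chunkRows, 80L)   # capped at nrow
    expect_identical(h5Layout(a)$chunkCols, 1L)
    expect_identical(as.matrix(a), m)
    expect_lte(attr(a, "peakBufferBytes"), 2^20)

    b <- rechunk(a, tempfile(fileext = ".h5"), chunkLayout("chunked", 1, 50),
                 budgetBytes = 2^20)
    expect_identical(as.matrix(b), m)              # involution on values
    expect_identical(elemType(b), "double")

    expect_error(rechunk(src, tempfile(fileext = ".h5"),
                         chunkLayout("chunked", 80, 1), budgetBytes = 100),
                 "budget")
})

test_that("integer content survives rechunking with its element type", {
    m <- randomDense(40, 30, "integer", 1, seed = 13)
    src <- asTempH5(openMatrix(m), layout = chunkLayout("chunked", 10, 30))
    out <- rechunk(src, tempfile(fileext = ".h5"),
                   chunkLayout("chunked", 40, 3), budgetBytes = 2^20)
    expect_identical(elemType(out), "integer")
    expect_identical(as.matrix(out), m)
})
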