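test_that("cscFromDense produces the canonical three-array encoding", {
    s <- cscFromDense(m3Matrix())
    a <- cscArrays(s)
    expect_equal(a$x, c(1, 2, 3, 4))
    expect_equal(a$i, c(0L, 2L, 1L, 2L))
    expect_equal(a$p, c(0L, 2L, 2L, 4L))

    z <- cscFromDense(matrix(0, 3, 3))
    expect_equal(cscArrays(z)$p, c(0L, 0L, 0L, 0L))
    expect_length(cscArrays(z)$x, 0)

    one <- cscFromDense(matrix(7, 1, 1))
    expect_equal(cscArrays(one), list(x = 7, i = 0L, p = c(0L, 1L)))

    expect_error(cscFromDense(matrix("a", 2, 2)), "sparse strings")
})

test_that("reconstructing dense from CSC reproduces the input exactly", {
    for (seed in 1:5) {
        m <- randomDense(37, 23, "double", 0.15, seed = seed)
        expect_identical(unname(as.matrix(cscFromDense(m))), m)
    }
})

test_that("column access scatters stored values over zeros", {
    s <- cscFromDense(m3Matrix())
    expect_equal(as.vector(getCol(s, 3)), c(0, 3, 4))
    expect_equal(as.vector(getCol(s, 2)), c(0, 0, 0))
    expect_equal(as.vector(getCol(s, 1, first = 2, last = 3)), c(0, 2))
    expect_error(getCol(s, 4), "out of range")
})

test_that("naive row access equals the dense oracle and never probes empty columns", {
    s <- cscFromDense(m3Matrix())
    expect_equal(as.vector(sparseRowNaive(s, 2)), c(0, 0, 3))
    expect_equal(as.vector(sparseRowNaive(s, 1)), c(1, 0, 0))

    z <- cscFromDense(matrix(0, 5, 4))
    pc <- newProbeCounter()
    expect_equal(as.vector(sparseRowNaive(z, 3, counter = pc)), rep(0, 4))
    expect_identical(probeReport(pc)$indexComparisons, 0)
})

test_that("cached row access equals naive row access for any access order", {
    for (seed in 1:6) {
        m <- randomDense(120, 17, "double", c(0.02, 0.1, 0.5)[seed %% 3 + 1],
                         seed = 200 + seed)
        orders <- list(seq_len(120), stridedOrder(120),
                       withr::with_seed(seed, sample.int(120)),
                       c(5, 5, 4, 120, 1, 60))   # repeats and jumps
        for (ord in orders) {
            s <- cscFromDense(m)   # fresh cache
            for (r in ord) {
                expect_identical(as.vector(getRow(s, r)),
                                 as.vector(sparseRowNaive(s, r)))
                expect_identical(as.vector(getRow(s, r)), unname(m[r, ]))
            }
        }
    }
})

test_that("a single cached request on a fresh cache equals the naive result", {
    s <- cscFromDense(randomDense(50, 9, "double", 0.2, seed = 9))
    expect_identical(as.vector(getRow(s, 6)), as.vector(sparseRowNaive(s, 6)))
})

test_that("consecutive sweeps respect the probe-economy bound and beat naive search", {
    s <- simulateSparse(2000, 200, density = 0.02, seed = 31)
    nnz <- length(cscArrays(s)$x)
    cached <- sparseSweep(s, seq_len(2000), "cached")
    naive <- sparseSweep(s, seq_len(2000), "naive")
    expect_identical(cached$rowTotals, naive$rowTotals)
    # each stored element is stepped past at most once per sweep
    expect_lte(cached$probes, nnz + 2000 * 200 + 200)
    expect_lt(cached$probes, naive$probes)
})

test_that("sweep counters are deterministic", {
    s <- simulateSparse(500, 40, density = 0.05, seed = 8)
    ord <- withr::with_seed(4, sample.int(500))
    a <- sparseSweep(s, ord, "cached")
    b <- sparseSweep(s, ord, "cached")
    expect_identical(a$probes, b$probes)
    expect_identical(a$rowTotals, b$rowTotals)
})

test_that("validateCSC reports the first violated invariant with its location", {
    expect_true(validateCSC(cscFromDense(m3Matrix())))
    expect_match(validateCSC(list(x = 1, i = 5L, p = c(0L, 1L),
                                  nrow = 3, ncol = 1)),
                 "row index out of range at offset 0")
    expect_match(validateCSC(list(x = c(1, 2, 3, 4), i = c(0L, 1L, 0L, 1L),
                                  p = c(0L, 2L, 1L, 4L), nrow = 3, ncol = 3)),
                 "p not nondecreasing at column 2")
    expect_match(validateCSC(list(x = c(1, 0), i = c(0L, 1L),
                                  p = c(0L, 2L), nrow = 3, ncol = 1)),
                 "stored zero")
    expect_match(validateCSC(list(x = c(1, 2), i = c(1L, 0L),
                                  p = c(0L, 2L), nrow = 3, ncol = 1)),
                 "not strictly increasing")
})

test_that("MatrixMarket ingest rejects duplicates and honours the field type", {
    f <- tempfile(fileext = ".mtx")
    writeLines(c("%%MatrixMarket matrix coordinate real general",
                 "3 3 3", "1 1 1.5", "1 1 2.5", "2 2 1"), f)
    expect_error(openMatrix(f), "duplicate")

    writeLines(c("%%MatrixMarket matrix coordinate integer general",
                 "3 2 2", "1 1 4", "3 2 9"), f)
    h <- openMatrix(f)
    expect_identical(elemType(h), "integer")
    expect_identical(getElem(h, 3, 2), 9L)

    writeLines(c("%%MatrixMarket matrix coordinate pattern general",
                 "2 2 2", "1 1", "2 2"), f)
    hp <- openMatrix(f)
    expect_identical(elemType(hp), "logical")
    expect_equal(unname(as.matrix(hp)), matrix(c(TRUE, FALSE, FALSE, TRUE), 2))
})
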