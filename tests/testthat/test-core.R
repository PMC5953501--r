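test_that("openMatrix dispatches on source and reports shape and type", {
    m3 <- m3Matrix()
    csv <- tempfile(fileext = ".csv")
    writeMatrix(openMatrix(m3), csv)
    h <- openMatrix(csv)
    expect_s4_class(h, "DenseMatrixHandle")
    expect_equal(dim(h), c(3L, 3L))
    expect_identical(repType(h), "dense")

    mtx <- tempfile(fileext = ".mtx")
    writeMatrix(cscFromDense(m3), mtx)
    hs <- openMatrix(mtx)
    expect_identical(repType(hs), "sparse_csc")
    expect_length(cscArrays(hs)$x, sum(m3 != 0))   # 4 stored values

    h5 <- tempfile(fileext = ".h5")
    writeMatrix(openMatrix(m3), h5)
    hh <- openMatrix(h5)
    expect_identical(repType(hh), "hdf5")
    expect_error(openMatrix(h5, dataset = "/nope"), "not found")
    expect_error(openMatrix(tempfile(fileext = ".csv")), "cannot open")
    expect_error(openMatrix(tempfile(fileext = ".xyz")), "extension")
})

test_that("accessors return the worked example's rows, columns and entries on every backend", {
    m3 <- m3Matrix()
    for (h in backendTrio(m3)) {
        expect_equal(as.vector(getRow(h, 2)), c(0, 0, 3))
        expect_equal(as.vector(getRow(h, 1)), c(1, 0, 0))
        expect_equal(as.vector(getCol(h, 1)), c(1, 0, 2))
        expect_equal(as.vector(getCol(h, 2)), c(0, 0, 0))
        expect_equal(as.vector(getRow(h, 3, first = 2, last = 3)), c(0, 4))
        expect_equal(getElem(h, 3, 3), 4)
        expect_equal(getElem(h, 1, 2), 0)
        expect_error(getElem(h, 4, 1), "out of range")
        expect_error(getCol(h, 4), "out of range")
        expect_error(getRow(h, 0), "out of range")
        expect_error(getRow(h, 1, first = 2, last = 5), "extent")
    }
})

test_that("accessor results agree with the dense oracle across backends, types and densities", {
    cases <- expand.grid(
        shape = list(c(1, 1), c(7, 13), c(40, 8), c(200, 300)),
        density = c(0, 0.01, 0.1, 1),
        elemtype = c("double", "integer", "logical"),
        stringsAsFactors = FALSE)
    # string matrices are always dense-valued
    cases <- rbind(cases,
        expand.grid(shape = list(c(1, 1), c(7, 13), c(40, 8)),
                    density = 1, elemtype = "string",
                    stringsAsFactors = FALSE))
    expect_gte(nrow(cases), 50)
    for (k in seq_len(nrow(cases))) {
        sh <- cases$shape[[k]]
        m <- randomDense(sh[1], sh[2], cases$elemtype[k], cases$density[k],
                         seed = 1000 + k)
        trio <- backendTrio(m)
        rows <- unique(round(seq(1, sh[1], length.out = min(sh[1], 12))))
        cols <- unique(round(seq(1, sh[2], length.out = min(sh[2], 12))))
        for (h in trio) {
            for (r in rows)
                expect_equal(as.vector(getRow(h, r)), unname(m[r, ]))
            for (cc in cols)
                expect_equal(as.vector(getCol(h, cc)), unname(m[, cc]))
            expect_equal(getElem(h, sh[1], sh[2]), unname(m[sh[1], sh[2]]))
        }
    }
})

test_that("entry, row and column access are mutually consistent", {
    m <- randomDense(11, 9, "double", 0.3, seed = 42)
    for (h in backendTrio(m)) {
        for (r in seq_len(11)) for (cc in seq_len(9)) {
            expect_identical(getElem(h, r, cc), getRow(h, r)[cc])
            expect_identical(getElem(h, r, cc), getCol(h, cc)[r])
        }
    }
})

test_that("partial extents match slices of the full vector", {
    m <- randomDense(15, 12, "double", 0.4, seed = 7)
    for (h in backendTrio(m)) {
        full <- getRow(h, 5)
        for (a in c(1, 3, 12)) for (b in c(a - 1, a, 7, 12)) {
            if (b < a - 1 || b > 12) next
            got <- getRow(h, 5, first = a, last = b)
            want <- if (b < a) full[0] else full[a:b]
            expect_equal(as.vector(got), as.vector(want))
        }
        fullc <- getCol(h, 3)
        expect_equal(getCol(h, 3, first = 4, last = 11), fullc[4:11])
        expect_length(getCol(h, 3, first = 2, last = 1), 0)
    }
})

test_that("returned copies are safe to mutate", {
    m <- randomDense(6, 6, "double", 1, seed = 3)
    for (h in backendTrio(m)) {
        v <- getRow(h, 2)
        v[] <- -99
        expect_equal(as.vector(getRow(h, 2)), unname(m[2, ]))
        w <- getCol(h, 4)
        w[1] <- 1e6
        expect_equal(as.vector(getCol(h, 4)), unname(m[, 4]))
    }
})

test_that("column views materialise to the copied column and are refused for file backends", {
    m3 <- m3Matrix()
    trio <- backendTrio(m3)
    expect_equal(materialiseView(getColView(trio$dense, 1)), c(1, 0, 2))
    sv <- getColView(trio$sparse_csc, 3)
    expect_equal(sv$values, c(3, 4))
    expect_equal(sv$rows, c(2, 3))
    expect_equal(materialiseView(sv), as.vector(getCol(trio$sparse_csc, 3)))
    expect_error(getColView(trio$hdf5, 1), "file-backed")
})

test_that("zero-extent matrices are valid and missing values are rejected", {
    e <- openMatrix(matrix(numeric(0), nrow = 0, ncol = 5))
    expect_equal(dim(e), c(0L, 5L))
    expect_length(getCol(e, 3), 0)
    expect_error(getRow(e, 1), "out of range")
    expect_error(openMatrix(matrix(c(1, NA, 3, 4), 2)), "missing values")
    bad <- tempfile(fileext = ".csv")
    writeLines(c("1,2", "3,NA"), bad)
    expect_error(openMatrix(bad), "missing values")
})

test_that("in-memory Matrix package sparse classes open without conversion", {
    m3 <- m3Matrix()
    h <- openMatrix(Matrix::Matrix(m3, sparse = TRUE))
    expect_identical(repType(h), "sparse_csc")
    expect_equal(unname(as.matrix(h)), m3)
    lg <- openMatrix(methods::as(Matrix::Matrix(m3 != 0, sparse = TRUE),
                                 "CsparseMatrix"))
    expect_identical(elemType(lg), "logical")
    expect_equal(as.vector(getRow(lg, 3)), c(TRUE, FALSE, TRUE))
})
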