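test_that("column and row sums match hand computation on every backend", {
    for (h in backendTrio(m3Matrix())) {
        expect_equal(colSums(h), c(3, 0, 7))
        expect_equal(rowSums(h), c(1, 3, 6))
    }
    z <- openMatrix(matrix(0, 4, 3))
    expect_equal(colSums(z), c(0, 0, 0))
    expect_error(colSums(openMatrix(matrix("a", 1, 1))), "numeric")
})

test_that("sums conserve the grand total and are backend-identical", {
    m <- randomDense(60, 45, "integer", 0.2, seed = 17)
    ref <- NULL
    for (h in backendTrio(m)) {
        cs <- colSums(h)
        rs <- rowSums(h)
        expect_equal(sum(cs), sum(rs))
        expect_equal(cs, unname(base::colSums(m)))
        if (is.null(ref)) ref <- cs else expect_identical(cs, ref)
    }
})

test_that("qc metrics on the worked example match exhaustive counts", {
    for (h in backendTrio(m3Matrix())) {
        rep <- qcMetrics(h, genesInRows = TRUE)
        expect_equal(librarySizes(rep), c(3, 0, 7))
        expect_equal(cellsPerGene(rep), c(1L, 1L, 2L))
        expect_equal(genesPerCell(rep), c(2L, 0L, 2L))
        expect_equal(nonzeroFraction(rep), 4 / 9)
    }
    zrep <- qcMetrics(openMatrix(matrix(0, 3, 2)))
    expect_equal(librarySizes(zrep), c(0, 0))
    expect_equal(nonzeroFraction(zrep), 0)
})

test_that("qc metrics equal brute-force counts on simulated count matrices", {
    for (seed in c(21, 22)) {
        s <- simulateCounts(300, 40, density = 0.15, lambda = 2, seed = seed)
        m <- as.matrix(s)
        rep <- qcMetrics(s)
        expect_equal(librarySizes(rep), unname(base::colSums(m)))
        expect_equal(cellsPerGene(rep),
                     unname(as.integer(base::rowSums(m > 0))))
        expect_equal(genesPerCell(rep),
                     unname(as.integer(base::colSums(m > 0))))
        expect_equal(nonzeroFraction(rep), sum(m != 0) / length(m))
        expect_equal(sum(cellsPerGene(rep)), sum(genesPerCell(rep)))
        # flipped orientation swaps the gene/cell roles
        flipped <- qcMetrics(s, genesInRows = FALSE)
        expect_equal(librarySizes(flipped), unname(base::rowSums(m)))
        expect_equal(cellsPerGene(flipped),
                     unname(as.integer(base::colSums(m > 0))))
    }
})

test_that("qc reports are identical across backends", {
    m <- as.matrix(simulateCounts(80, 25, density = 0.2, seed = 33))
    reports <- lapply(backendTrio(m), qcMetrics)
    for (rep in reports[-1]) {
        expect_identical(librarySizes(rep), librarySizes(reports[[1]]))
        expect_identical(cellsPerGene(rep), cellsPerGene(reports[[1]]))
        expect_identical(genesPerCell(rep), genesPerCell(reports[[1]]))
    }
})

test_that("metrics serialise to TSV with a summary line", {
    s <- simulateCounts(20, 10, density = 0.3, seed = 2)
    f <- tempfile(fileext = ".tsv")
    writeMetricsTSV(qcMetrics(s), f)
    lines <- readLines(f)
    expect_match(lines[1], "^# dims=20x10 nnz=60 ")
    expect_identical(lines[2], "section\tindex\ttotal\tdetected")
    expect_length(grep("^gene\t", lines), 20)
    expect_length(grep("^cell\t", lines), 10)
})

test_that("naive multiplication through accessors matches the identity and brute force", {
    m3 <- m3Matrix()
    s <- cscFromDense(m3)
    expect_equal(unname(as.matrix(matmulNaive(openMatrix(m3),
                                              openMatrix(diag(3))))), m3)
    # brute-force triple loop oracle
    brute <- matrix(0, 3, 3)
    for (r in 1:3) for (cc in 1:3) for (k in 1:3)
        brute[r, cc] <- brute[r, cc] + m3[r, k] * m3[k, cc]
    expect_equal(brute, matrix(c(1, 6, 10, 0, 0, 0, 0, 12, 16), 3))
    for (A in backendTrio(m3)) {
        prod <- matmulNaive(A, openMatrix(m3))
        expect_equal(unname(as.matrix(prod)), brute)
        # output representation matches the first operand
        expect_identical(repType(prod),
                         matchOutputRepresentation(repType(A),
                                                   "double")$representation)
    }
    expect_error(matmulNaive(openMatrix(matrix(0, 2, 3)),
                             openMatrix(matrix(0, 4, 2))),
                 "non-conformable")
})

test_that("sparse multiplication equals the naive product within 1e-10", {
    m3 <- m3Matrix()
    expect_equal(unname(as.matrix(matmulSparse(cscFromDense(m3),
                                               cscFromDense(m3)))),
                 matrix(c(1, 6, 10, 0, 0, 0, 0, 12, 16), 3))
    for (seed in 1:5) {
        a <- randomDense(30, 30, "double", 0.05, seed = 400 + seed)
        b <- randomDense(30, 30, "double", 0.05, seed = 500 + seed)
        got <- as.matrix(matmulSparse(cscFromDense(a), cscFromDense(b)))
        expect_lt(max(abs(got - a %*% b)), 1e-10)
    }
    z <- matmulSparse(cscFromDense(m3), cscFromDense(matrix(0, 3, 3)))
    expect_length(cscArrays(z)$x, 0)
})

test_that("sparse multiplication touches only stored operand entries", {
    a <- randomDense(40, 40, "double", 0.05, seed = 61)
    b <- randomDense(40, 40, "double", 0.05, seed = 62)
    A <- cscFromDense(a)
    B <- cscFromDense(b)
    pc <- newProbeCounter()
    matmulSparse(A, B, counter = pc)
    # expected multiply-adds: sum over stored B[k, j] of nnz(A[, k])
    nnzAcol <- diff(cscArrays(A)$p)
    innerK <- cscArrays(B)$i + 1L
    expect_identical(probeReport(pc)$multiplyAdds,
                     as.double(sum(nnzAcol[innerK])))
    expect_lt(probeReport(pc)$multiplyAdds, 40^3)
})
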