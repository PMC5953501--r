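# Benchmark harness. Wall-clock means are reported for orientation but the
# contractual performance surface is the probe instrumentation: row-index
# comparisons for sparse access and chunk fetches for HDF5 access, which
# are identical across machines and across repeated runs with one seed.

BENCH_PATTERNS <- c("consecutive_rows", "consecutive_cols", "strided_rows",
                    "random_rows", "random_cols")

# visit order over n items: consecutive, strided (every `stride`-th, then
# return to the first unvisited: 1, 1+s, ..., 2, 2+s, ...), or a seeded
# uniform permutation visiting each exactly once
sweepOrder <- function(n, pattern, stride = 5L, seed = 1L) {
    switch(pattern,
        consecutive = seq_len(n),
        strided = {
            if (n == 0L) integer(0)
            else unlist(lapply(seq_len(min(stride, n)),
                               function(s) seq.int(s, n, by = stride)))
        },
        random = withSeed(seed, sample.int(n)),
        stop("unknown order kind '", pattern, "'"))
}

#' Run a seeded access-pattern benchmark on a matrix handle
#'
#' @description
#' Executes a full access sweep -- every row (or column) of the matrix,
#' each exactly once, in consecutive, strided or seeded-random order --
#' `iterations` times, timing each pass and recording the probe counts of
#' a single pass. For sparse handles and row patterns, both the cached and
#' the naive binary-search row paths are benchmarked so their comparison
#' counts can be compared directly. For HDF5 handles the chunk cache is
#' emptied before each pass, so fetch counts reflect the configured cache
#' parameters alone.
#'
#' @param h a [MatrixHandle-class].
#' @param pattern one of `"consecutive_rows"`, `"consecutive_cols"`,
#'   `"strided_rows"` (every `stride`-th row, returning to the first
#'   unvisited), `"random_rows"`, `"random_cols"`.
#' @param iterations number of timed passes (counts come from one pass).
#' @param seed seed for random visit orders.
#' @param stride stride for `"strided_rows"`.
#' @param verify if `TRUE`, every accessed vector is checked against the
#'   dense oracle (`as.matrix` of the handle); an error is raised on any
#'   mismatch. Intended for small fixtures.
#' @return a data.frame with one row per benchmarked method: columns
#'   `backend`, `method`, `pattern`, `iterations`, `mean_seconds`,
#'   `index_comparisons`, `chunk_fetches`.
#' @examples
#' s <- simulateSparse(500, 50, density = 0.05, seed = 3)
#' runBench(s, "consecutive_rows", iterations = 2)
#' @export
runBench <- function(h, pattern = "consecutive_rows", iterations = 10L,
                     seed = 1L, stride = 5L, verify = FALSE) {
    stopifnot(is(h, "MatrixHandle"))
    pattern <- match.arg(pattern, BENCH_PATTERNS)
    byRow <- pattern != "consecutive_cols" && pattern != "random_cols"
    n <- if (byRow) nrow(h) else ncol(h)
    kind <- sub("_(rows|cols)$", "", pattern)
    ord <- sweepOrder(n, kind, stride = stride, seed = seed)
    oracle <- if (verify) as.matrix(h)

    methods <- if (is(h, "SparseMatrixHandle") && byRow)
        c("cached", "naive") else "accessor"
    rows <- lapply(methods, function(method) {
        secs <- numeric(iterations)
        probes <- 0
        fetches <- 0
        for (it in seq_len(iterations)) {
            pc <- newProbeCounter()
            if (is(h, "SparseMatrixHandle") && byRow) {
                # fresh cache per pass; C++ sweep for speed
                t0 <- proc.time()[["elapsed"]]
                res <- sparseSweep(h, ord, method = method)
                secs[it] <- proc.time()[["elapsed"]] - t0
                pc$indexComparisons <- res$probes
                if (verify) {
                    want <- vapply(ord, function(r) sum(as.double(oracle[r, ])),
                                   numeric(1))
                    if (!isTRUE(all.equal(res$rowTotals, want)))
                        stop("benchmark sweep disagrees with the dense oracle")
                }
            } else {
                if (is(h, "HDF5MatrixHandle")) resetChunkCacheStore(h@state)
                t0 <- proc.time()[["elapsed"]]
                for (idx in ord) {
                    v <- if (byRow) getRow(h, idx, counter = pc)
                         else getCol(h, idx, counter = pc)
                    if (verify) {
                        want <- if (byRow) oracle[idx, ] else oracle[, idx]
                        if (!identical(as.vector(v), as.vector(want)))
                            stop("benchmark sweep disagrees with the dense oracle")
                    }
                }
                secs[it] <- proc.time()[["elapsed"]] - t0
            }
            if (it == 1L) {
                probes <- pc$indexComparisons
                fetches <- pc$chunkFetches
            }
        }
        data.frame(backend = repType(h), method = method, pattern = pattern,
                   iterations = iterations, mean_seconds = mean(secs),
                   index_comparisons = probes, chunk_fetches = fetches,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
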