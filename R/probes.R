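#' Probe counters: hardware-independent access-cost instrumentation
#'
#' @description
#' Wall-clock timings of matrix access depend on the machine; the package
#' instead counts the elementary operations that dominate access cost and
#' asserts on those. A probe counter accumulates:
#' \describe{
#'   \item{`indexComparisons`}{comparisons between a stored CSC row index
#'     and the requested row -- one per index examined during a binary
#'     search or a cached pointer advance.}
#'   \item{`chunkFetches`}{HDF5 chunks actually read from file (chunk-cache
#'     hits are not counted).}
#'   \item{`multiplyAdds`}{scalar multiply-add operations performed by
#'     [matmulSparse()].}
#' }
#' Counters are monotonically nondecreasing between resets, and identical
#' access sequences on identical handles yield identical counts.
#'
#' @return `newProbeCounter()` an environment with the three counters at
#'   zero; `probeReport()` a named list of the current counts;
#'   `resetProbes()` the counter, zeroed, invisibly.
#'
#' @examples
#' pc <- newProbeCounter()
#' h <- cscFromDense(matrix(c(1, 0, 2, 0, 0, 0, 0, 3, 4), nrow = 3))
#' getRow(h, 2, counter = pc)
#' probeReport(pc)$indexComparisons
#' @export
newProbeCounter <- function() {
    pc <- new.env(parent = emptyenv())
    pc$indexComparisons <- 0
    pc$chunkFetches <- 0
    pc$multiplyAdds <- 0
    class(pc) <- "ProbeCounter"
    pc
}

#' @rdname newProbeCounter
#' @param counter a counter from `newProbeCounter()`.
#' @export
probeReport <- function(counter) {
    list(indexComparisons = counter$indexComparisons,
         chunkFetches = counter$chunkFetches,
         multiplyAdds = counter$multiplyAdds)
}

#' @rdname newProbeCounter
#' @export
resetProbes <- function(counter) {
    counter$indexComparisons <- 0
    counter$chunkFetches <- 0
    counter$multiplyAdds <- 0
    invisible(counter)
}

#' @export
print.ProbeCounter <- function(x, ...) {
    cat(sprintf(
        "<ProbeCounter> index comparisons: %g, chunk fetches: %g, multiply-adds: %g\n",
        x$indexComparisons, x$chunkFetches, x$multiplyAdds))
    invisible(x)
}
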