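# Seeded fixture generator. Sparsity patterns use exact-count sampling --
# exactly round(density * nrow * ncol) nonzero positions, uniform without
# replacement -- so the nonzero count of a fixture is deterministic, not
# merely expected. The RNG state of the caller's session is saved and
# restored around every draw.

VALUE_MODELS <- c("unit_normal_abs", "uniform_int_1_100",
                  "count_1_plus_poisson")

withSeed <- function(seed, expr) {
    genv <- globalenv()
    had <- exists(".Random.seed", envir = genv, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = genv)
    on.exit({
        if (had) assign(".Random.seed", old, envir = genv)
        else if (exists(".Random.seed", envir = genv, inherits = FALSE))
            rm(".Random.seed", envir = genv)
    })
    set.seed(as.integer(seed))
    expr
}

drawValues <- function(n, model, lambda) {
    v <- switch(model,
        unit_normal_abs = abs(stats::rnorm(n)),
        uniform_int_1_100 = as.double(sample.int(100L, n, replace = TRUE)),
        count_1_plus_poisson = 1 + stats::rpois(n, lambda))
    v[v == 0] <- 1   # keep sparse stores free of stored zeros
    v
}

defaultModel <- function(elemtype) {
    switch(elemtype, double = "unit_normal_abs",
           integer = "uniform_int_1_100", logical = "unit_normal_abs",
           string = "unit_normal_abs")
}

checkSimSpec <- function(nrow, ncol, density, elemtype, model, lambda, seed) {
    if (nrow < 0 || ncol < 0) stop("dimensions must be nonnegative")
    if (is.na(density) || density < 0 || density > 1)
        stop("density must be in [0, 1]")
    if (!elemtype %in% ELEM_TYPES)
        stop("unsupported element type '", elemtype, "'")
    if (!model %in% VALUE_MODELS) stop("unknown value model '", model, "'")
    if (lambda <= 0) stop("lambda must be positive")
    if (is.na(as.integer(seed))) stop("seed must be an integer")
}

#' Simulate matrices with controlled shape, density and value law
#'
#' @description
#' `simulateDense()` draws a dense matrix; `simulateSparse()` a CSC matrix
#' with exactly `round(density * nrow * ncol)` nonzero entries at
#' uniformly sampled positions; `simulateCounts()` a CSC integer matrix of
#' single-cell-like counts whose nonzero values are `1 + Poisson(lambda)`
#' (so every stored count is at least 1, as for a detected gene). All
#' three are deterministic in `seed` and leave the session RNG state
#' untouched.
#'
#' Value models: `"unit_normal_abs"` (|N(0,1)|, mean `sqrt(2/pi)`),
#' `"uniform_int_1_100"` (uniform integers 1-100),
#' `"count_1_plus_poisson"` (`1 + Poisson(lambda)`). Logical matrices
#' store 1 at every sampled position.
#'
#' @param nrow,ncol dimensions.
#' @param density fraction of nonzero entries in \[0, 1\].
#' @param elemtype element type tag.
#' @param model value model; default chosen from `elemtype`.
#' @param lambda Poisson mean for `"count_1_plus_poisson"`.
#' @param seed integer seed; equal seeds give identical matrices.
#' @return a `DenseMatrixHandle` or [SparseMatrixHandle-class].
#' @examples
#' s <- simulateSparse(100, 50, density = 0.01, seed = 7)
#' length(cscArrays(s)$x)   # exactly 50
#' @export
simulateDense <- function(nrow, ncol, elemtype = "double", density = 1,
                          model = NULL, lambda = 1, seed = 1) {
    if (is.null(model)) model <- defaultModel(elemtype)
    checkSimSpec(nrow, ncol, density, elemtype, model, lambda, seed)
    if (elemtype == "string" && density < 1)
        stop("string matrices must be dense (density = 1)")
    n <- as.double(nrow) * ncol
    withSeed(seed, {
        if (elemtype == "string") {
            data <- sprintf("s%06d", sample.int(1000000L, n, replace = TRUE))
        } else {
            v <- drawValues(n, model, lambda)
            if (elemtype == "logical") v <- rep(1, n)
            if (density < 1) {
                nnz <- round(density * n)
                zero <- rep(TRUE, n)
                if (nnz > 0) zero[sample.int(n, nnz)] <- FALSE
                v[zero] <- 0
            }
            data <- castToElem(v, elemtype)
        }
        newDenseHandle(data, nrow, ncol, elemtype)
    })
}

#' @rdname simulateDense
#' @export
simulateSparse <- function(nrow, ncol, density = 0.01, elemtype = "double",
                           model = NULL, lambda = 1, seed = 1) {
    if (is.null(model)) model <- defaultModel(elemtype)
    checkSimSpec(nrow, ncol, density, elemtype, model, lambda, seed)
    if (elemtype == "string") stop("sparse strings unsupported")
    n <- as.double(nrow) * ncol
    nnz <- round(density * n)
    withSeed(seed, {
        pos <- if (nnz > 0) sort(sample.int(n, nnz)) else integer(0)
        i1 <- as.integer((pos - 1) %% nrow) + 1L
        j1 <- as.integer((pos - 1) %/% nrow) + 1L
        v <- if (elemtype == "logical") rep(1, nnz)
             else drawValues(nnz, model, lambda)
        sparseFromTriplets(i1, j1, v, nrow, ncol, elemtype)
    })
}

#' @rdname simulateDense
#' @export
simulateCounts <- function(nrow, ncol, density = 0.1, lambda = 1, seed = 1) {
    simulateSparse(nrow, ncol, density = density, elemtype = "integer",
                   model = "count_1_plus_poisson", lambda = lambda,
                   seed = seed)
}
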