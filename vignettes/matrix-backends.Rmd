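---
title: "One accessor contract over dense, sparse and HDF5-backed matrices"
author: "omnimat authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{One accessor contract over dense, sparse and HDF5-backed matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omnimat)
```

## The problem

A transcriptomics experiment yields a matrix of expression values — genes
in rows, samples or cells in columns. Depending on its size and sparsity,
that matrix is best held as an ordinary dense array, as a compressed
sparse column (CSC) matrix storing only nonzeros, or in a chunked HDF5
file read piecewise from disk. Code that loops over genes or cells should
not care which of these it was handed. `omnimat` fixes one accessor
contract — `getRow()`, `getCol()`, `getElem()` — and implements it over
all three representations, so that any computation written against the
contract (the package's own QC metrics, reductions and multiplication
included) returns identical results on every backend.

The core guarantees:

* **Copy on access.** `getRow()`/`getCol()` return freshly allocated
  vectors; callers can modify them freely and never observe buffer reuse.
  `getColView()` is the deliberate exception for read-only column access
  on in-memory backends; R's value semantics make the view immutable by
  construction, and file-backed handles refuse it.
* **Backend equivalence.** For equal logical content, every accessor
  returns bitwise-equal values on every backend; the dense representation
  is the ground truth the test suite compares against.
* **Immutability of handles.** A handle never changes after opening;
  caches beneath it (the sparse row cache, the HDF5 chunk cache) affect
  cost, never values.

Indexing at the R interface is 1-based with closed extents
`[first, last]`, as R users expect; the internal C++ arrays and the
on-disk MatrixMarket conversion use the conventional 0-based CSC
encoding. `last = first - 1` denotes an empty extent, so adjacent slices
compose without bookkeeping.

## Cached sparse row access

Column access on a CSC store is a contiguous slice, but a row access must
locate the requested row in each column's sorted index run. The naive
method binary-searches every column from scratch: about
$\log_2(\mathrm{nnz}_c)$ index comparisons per column per row. Row sweeps
— the dominant pattern when computing per-gene statistics — repeat almost
all of that work, because consecutive rows land at the same or adjacent
offsets.

The cached method keeps one pointer per column, positioned at the lower
bound of the previously served row, plus the previous row index. Serving
row $r$ after row $r_0$:

* $r = r_0 + 1$: advance the pointer linearly past indices $< r$
  (typically zero or one steps);
* $r > r_0$: binary-search only the range above the pointer;
* $r < r_0$ or no history: binary-search only the range below (a fresh
  cache initialises pointers to the column ends, so the first request
  searches the full column, exactly like the naive method).

After every request the pointer is the lower bound of $r$, so the rule
above is self-maintaining, and over a full ascending sweep each stored
element is stepped past at most once. The cost unit asserted in the tests
is the *probe* — one examination of a stored row index against the
requested row — counted identically in both paths. A full consecutive
sweep costs at most $\mathrm{nnz} + nm$ probes cached (one terminal
examination per row-column pair plus the element steps) versus roughly
$nm(\log_2 d n + 1)$ naive; on the 10000×1000, 1%-dense fixture that is a
measured ~7.7-fold reduction, comfortably beyond the 2-fold margin the
acceptance suite requires. Ordered-but-strided and random orders still
benefit, because every search is confined to one side of the pointer.

Partial-extent row requests bypass the cache (they would desynchronise
pointers of unvisited columns) and use the naive search; correctness is
unaffected and full-extent sweeps, the pattern the cache exists for, keep
their guarantee.

## HDF5 backend and chunk-cache tuning

An HDF5-backed handle stores only the file geometry in memory; data move
in chunks, the atomic I/O unit of the format. The package maintains its
own chunk cache — keyed by chunk coordinates, LRU eviction under a byte
budget, capped by the slot count — rather than relying on the HDF5
library's internal cache. That choice is what makes the performance
surface *assertable*: chunk fetches are counted at the cache boundary,
and the tuned-cache guarantee below is a test, not a hope. (`w0`, the
preemption weight of the classic HDF5 parameterisation, is recorded for
fidelity; with whole-stripe capacities LRU already realises the behaviour
it asks for.)

`tuneChunkCache()` sizes the cache for sweeps: a full consecutive row
sweep touches one horizontal stripe of chunks at a time, so capacity is
set to exactly one stripe — $\lceil m / c_{\mathrm{cols}}\rceil$ chunks —
with a prime slot count at least 100× the stripe's chunk count. During a
tuned sweep each chunk is fetched exactly once (625 fetches for a
1000×1000 matrix in 40×40 chunks); an undersized cache of a single chunk
refetches the whole stripe on every row (≥ 25000 fetches). Rectangular
chunks plus a tuned cache thus serve row *and* column sweeps from one
layout.

`chooseChunkDims()` picks layouts at creation time: square 100×100-capped
chunks for sequential or mixed access; single-row (or single-column)
chunks of up to 5000 values for random access, so a random row fetch
reads no unrequested data. `rechunk()` converts between layouts by
streaming row blocks sized to a memory budget (block height aligned to
the destination's chunk rows when the budget allows); the planner's peak
buffer accounting is returned on the result and asserted in tests.
Datasets are written uncompressed by default (an optional gzip level is
available): the layout experiments this package supports are about
chunking, not compression. Dimension 0 is rows and dimension 1 columns;
the library's element order inside a chunk is invisible through the API.
Builders targeting HDF5 write blocks straight through the file API as
they arrive — the read-side cache is the tuned, counted surface.

## Output builders and representation matching

`makeBuilder()` constructs results incrementally in any representation;
`matchOutputRepresentation()` picks that representation from the input's:
dense in, dense out; HDF5 in, HDF5 out (a result of similar size belongs
on file); sparse in, sparse out where a sparse class exists for the
element type — logical and double only, mirroring `lgCMatrix`/`dgCMatrix`
— and dense otherwise. Sparse builders journal triplets and resolve
overlapping writes last-wins at finalisation, then drop zeros, so written
zeros never become stored values but do erase earlier nonzeros.

## Element types and missing values

Four element types run through everything: `integer` (32-bit), `logical`
(restricted to 0/1), `double`, and `string` (UTF-8; variable-length in
HDF5, dense-only in sparse contexts). Missing values are rejected at
ingest everywhere: the accessor contract has no NA semantics, and
silently propagating them through three backends with different native
missing-value conventions invites quiet corruption. Reductions and
metrics accumulate in double precision regardless of element type, so
integer count matrices cannot overflow 32-bit sums. In MatrixMarket
files, duplicate coordinates are an error rather than being summed —
summation is what the format's lenient readers do, and it masks upstream
bugs. "Detected"/"expressed" in the QC metrics means strictly positive.

## The simulator and what it does (not) show

`simulateDense()`/`simulateSparse()` generate the fixtures all properties
are tested on: exact-count sparsity (exactly `round(density * n * m)`
nonzero positions, uniform without replacement — deterministic nonzero
counts make the acceptance checks exact), values from |N(0,1)|, uniform
integers 1–100, or `1 + Poisson(λ)` for count matrices (every stored
count ≥ 1, as for a detected gene; λ defaults to 1, giving mean count 2
among detected entries). Default fixture sizes follow the simulation
conditions the methods were designed around: 10000×1000 at 1% density for
sparse row-access properties, 1000×1000 in 40×40 chunks for the tuned
cache, 2000×500 for rechunking. The simulator reproduces sparsity
*pattern* and value *scale* only; it has no gene-specific dispersions,
dropout curves or cell structure, so passing tests certify the access
machinery and the metric definitions, not any biological realism of the
values.

## Numerical and design notes

* Probe counts, fetch counts and simulated fixtures are integer-seeded
  and platform-independent; wall-clock times are reported by `runBench()`
  but never asserted.
* `matmulSparse()` (Gustavson accumulation) agrees with the
  accessor-driven naive product to ≤ 1e-10 absolute on the tested
  fixtures; its multiply-add count — $\sum_j \sum_{k : B_{kj} \ne 0}
  \mathrm{nnz}(A_{\cdot k})$ — is instrumented and asserted.
* Ties in builders resolve last-write-wins; interleaved row and column
  writes are allowed.
* Zero-extent matrices are valid everywhere; zero-density simulations
  yield valid empty CSC stores (`p` all zeros).
* All dense sources normalise to one column-major store; class provenance
  of equivalent dense inputs is not preserved.

## Limitations

* No delayed arithmetic, no subsetted/transposed views as handles, no
  compressed sparse row stores, no concurrent writers.
* The CLI (`exec/omnimat`, or `omnimatCLI()`) wraps the library 1:1 and
  adds nothing semantically.
* The HDF5 backend targets one 2-D dataset per handle; dialect formats
  (Loom, 10x HDF5) are out of scope.
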