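#' @include filter-io.R
NULL

## Per-element hash material for a scheme, independent of the filter size:
## alpha/beta as 8-byte-per-element raw blocks *before* the h_beta
## restriction (which depends on M and is applied at measurement time).
## Fingerprints are computed once here, which keeps size sweeps cheap.
.hashMaterial <- function(corpus, scheme, fpCache = NULL) {
    scheme <- HashScheme(scheme)
    if (scheme@name == "fp") {
        kinds <- scheme@parameters$kinds
        nb <- scheme@parameters$nbits
        u64 <- function(kind) {
            if (!is.null(fpCache) && !is.null(fpCache[[kind]]))
                fpCache[[kind]]
            else cpp_fp_to_u64(moleculeFingerprints(corpus, kind,
                                                    nbits = nb))
        }
        list(alpha = u64(kinds[1L]), beta = u64(kinds[2L]))
    } else {
        .stringHashBatch(corpus, scheme@name, M = NULL)
    }
}

## Precompute the 64-bit fingerprint reductions of a corpus once per kind,
## for sweeps that compare several fingerprint-pair schemes.
.fpU64Cache <- function(corpus, kinds, nbits = 2048) {
    out <- lapply(kinds, function(kind)
        cpp_fp_to_u64(moleculeFingerprints(corpus, kind, nbits = nbits)))
    names(out) <- kinds
    out
}

.sliceHashes <- function(material, i) {
    idx <- rep((i - 1L) * 8L, each = 8L) + seq_len(8)
    list(alpha = material$alpha[idx], beta = material$beta[idx])
}

.fprAtSize <- function(buildH, queryH, M, k) {
    bits <- raw(ceiling(M / 8))
    bits <- cpp_bloom_set(bits, buildH$alpha,
                          cpp_enforce_beta(buildH$beta, M), k, M)
    mean(cpp_bloom_check(bits, queryH$alpha,
                         cpp_enforce_beta(queryH$beta, M), k, M))
}

#' Empirical false-positive rate by the fifty-fifty split protocol
#'
#' Shuffles a deduplicated corpus with the given seed, adds the first half
#' to an empty filter of `M` bits, queries the disjoint second half, and
#' returns the fraction of positives -- all positives among the second half
#' are false positives by construction. The hash count is
#' `numHashes(M, n_build)`. The corpus is expected to be unique in the
#' hashed representation (canonical SMILES for molecule schemes); byte-wise
#' duplicates are removed before splitting, since a true member leaking into
#' the query half would not be a false positive.
#'
#' @param corpus character vector of (canonical) SMILES or byte strings,
#'   length >= 2 after deduplication.
#' @param M filter size in bits.
#' @param scheme hashing scheme name or [HashScheme-class].
#' @param seed RNG seed fixing the shuffle.
#' @return empirical false-positive rate in \code{[0, 1]}.
#' @examples
#' corpus <- generateCorpus(200, seed = 3, mode = "bytes")
#' fiftyFiftyFpr(corpus, M = requiredBits(100, 1e-6), scheme = "fnv",
#'               seed = 1)  # ~0
#' @export
fiftyFiftyFpr <- function(corpus, M, scheme = "fnv", seed = 1) {
    corpus <- unique(corpus)
    stopifnot(length(corpus) >= 2L, M >= 1)
    perm <- withSeed(seed, sample.int(length(corpus)))
    half <- floor(length(corpus) / 2)
    material <- .hashMaterial(corpus, scheme)
    buildH <- .sliceHashes(material, perm[seq_len(half)])
    queryH <- .sliceHashes(material, perm[(half + 1L):length(corpus)])
    k <- numHashes(M, half)
    .fprAtSize(buildH, queryH, M, k)
}

#' False-positive-rate sweep across filter sizes
#'
#' Runs the fifty-fifty protocol at each size with one shared shuffle/split,
#' so the curves of different sizes (and of different schemes at the same
#' seed) are directly comparable. Fingerprints are computed once per scheme.
#' String schemes produce smooth, monotonically decreasing curves tracking
#' the theoretical rate; fingerprint schemes sit above them and show noisy
#' peaks, the signature of structure-correlated, non-avalanching hashes.
#'
#' @param corpus character vector as in [fiftyFiftyFpr()].
#' @param scheme hashing scheme name or [HashScheme-class].
#' @param sizes strictly increasing vector of filter sizes M in bits.
#' @param seed RNG seed fixing the shared shuffle.
#' @param fpCache optional per-kind cache of 64-bit fingerprint reductions
#'   (internal use: lets multi-scheme comparisons fingerprint the corpus
#'   once per kind).
#' @return an [FprReport-class].
#' @export
sizeSweep <- function(corpus, scheme = "fnv", sizes, seed = 1,
                      fpCache = NULL) {
    corpus <- unique(corpus)
    stopifnot(length(corpus) >= 2L, length(sizes) >= 1L)
    if (any(diff(sizes) <= 0)) stop("'sizes' must be strictly increasing")
    scheme <- HashScheme(scheme)
    perm <- withSeed(seed, sample.int(length(corpus)))
    half <- floor(length(corpus) / 2)
    material <- .hashMaterial(corpus, scheme, fpCache = fpCache)
    buildH <- .sliceHashes(material, perm[seq_len(half)])
    queryH <- .sliceHashes(material, perm[(half + 1L):length(corpus)])
    emp <- theo <- numeric(length(sizes))
    for (j in seq_along(sizes)) {
        M <- sizes[j]
        k <- numHashes(M, half)
        emp[j] <- .fprAtSize(buildH, queryH, M, k)
        theo[j] <- theoreticalFpr(M, k, half)
    }
    new("FprReport", scheme = scheme, sizes = as.numeric(sizes),
        empiricalFpr = emp, theoreticalFpr = theo, nBuild = half,
        nQuery = length(corpus) - half, seed = as.numeric(seed))
}

#' @describeIn sizeSweep tabular view of a sweep report.
#' @param x an [FprReport-class].
#' @param ... unused.
#' @importFrom BiocGenerics as.data.frame
#' @export
setMethod("as.data.frame", "FprReport", function(x, ...) {
    data.frame(scheme = schemeLabel(x@scheme), M = x@sizes,
               bitsPerElement = x@sizes / x@nBuild,
               empiricalFpr = x@empiricalFpr,
               theoreticalFpr = x@theoreticalFpr)
})

setMethod("show", "FprReport", function(object) {
    cat(sprintf(
        "FprReport: scheme %s, %d size(s), n_build = %g, n_query = %g, seed = %g\n",
        schemeLabel(object@scheme), length(object@sizes), object@nBuild,
        object@nQuery, object@seed))
    print(as.data.frame(object), row.names = FALSE)
})

#' Bloom filter sizing table for chemical libraries
#'
#' Applies the sizing rule to a set of library sizes at one target
#' false-positive rate, reporting bits, bytes, GB under both byte
#' conventions (2^30 bytes and 10^9 bytes per GB, labelled), and the hash
#' count. At `epsilon = 0.005` every row uses 8 hash functions; libraries
#' from hundreds of thousands to billions of molecules need only MBs to a
#' few GB.
#'
#' @param n numeric vector of library sizes (each >= 1).
#' @param names optional library names (defaults to `names(n)` or `n`).
#' @param epsilon target false-positive rate.
#' @return data.frame with columns `name`, `n`, `bits`, `bytes`,
#'   `gb_2pow30`, `gb_1e9`, `k`.
#' @examples
#' sizingTable(c(ChemBL = 2354965, PubChem = 113993087))
#' @export
sizingTable <- function(n, names = NULL, epsilon = 0.005) {
    stopifnot(is.numeric(n), all(n >= 1))
    if (is.null(names))
        names <- if (!is.null(base::names(n))) base::names(n)
                 else format(n, scientific = FALSE, trim = TRUE)
    bits <- requiredBits(n, epsilon)
    data.frame(name = names, n = n, bits = bits, bytes = bits / 8,
               gb_2pow30 = bits / 8 / 2^30, gb_1e9 = bits / 8 / 1e9,
               k = numHashes(bits, n))
}

#' Query-latency micro-benchmark
#'
#' Times membership queries against a filter, separately for the raw hash
#' lookup and for canonicalize-plus-lookup (the full cost of querying an
#' arbitrary SMILES spelling). Probe order is seeded and reproducible;
#' latencies are hardware-dependent and are reported, never asserted.
#'
#' @param filter a [BloomFilter-class].
#' @param probes character vector of query strings.
#' @param repetitions number of timed repetitions (>= 1).
#' @param seed RNG seed fixing the probe order.
#' @return data.frame with one row per step (`query`,
#'   `canonicalize+query`): median and p95 per-query latency in
#'   microseconds across repetitions.
#' @importFrom stats quantile median
#' @export
queryBenchmark <- function(filter, probes, repetitions = 3, seed = 1) {
    stopifnot(is(filter, "BloomFilter"), is.character(probes),
              length(probes) >= 1L)
    if (repetitions < 1) stop("'repetitions' must be at least 1")
    probes <- withSeed(seed, sample(probes))
    raw.filter <- filter
    raw.filter@canonicalized <- FALSE
    perQuery <- function(f) {
        vapply(seq_len(repetitions), function(r) {
            t0 <- proc.time()[["elapsed"]]
            invisible(bloomContains(f, probes))
            (proc.time()[["elapsed"]] - t0) / length(probes) * 1e6
        }, numeric(1))
    }
    tRaw <- perQuery(raw.filter)
    can.filter <- filter
    can.filter@canonicalized <- TRUE
    tCan <- perQuery(can.filter)
    data.frame(step = c("query", "canonicalize+query"),
               median_us = c(median(tRaw), median(tCan)),
               p95_us = c(quantile(tRaw, 0.95), quantile(tCan, 0.95)),
               repetitions = repetitions, nProbes = length(probes),
               row.names = NULL)
}
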