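#' @include AllClasses.R AllGenerics.R
NULL

.LN2SQ <- log(2)^2

#' Bits required for a target false-positive rate
#'
#' Sizes a Bloom filter for `n` expected elements at false-positive rate
#' `epsilon`: \eqn{M = \lceil -n \ln\epsilon / (\ln 2)^2 \rceil} bits.
#' Monotone increasing in `n` and decreasing in `epsilon`. Storing the two
#' billion plus molecules of a purchasability library at `epsilon = 0.005`
#' needs under 3 GB; a few-million-compound library fits in a few MB.
#'
#' @param n expected number of elements (>= 0). May exceed 2^31; the result
#'   is returned as a double with exact integer value.
#' @param epsilon target false-positive rate, strictly between 0 and 1.
#' @return number of bits (numeric, integer-valued).
#' @examples
#' requiredBits(2354965, 0.005)            # ~26 M bits, ~3.1 MB
#' requiredBits(2354965, 0.005) / 8 / 2^30 # in GB (2^30-byte convention)
#' @export
requiredBits <- function(n, epsilon) {
    stopifnot(is.numeric(n), is.numeric(epsilon))
    if (any(n < 0)) stop("'n' must be non-negative")
    if (any(epsilon <= 0 | epsilon >= 1))
        stop("'epsilon' must lie strictly between 0 and 1")
    ceiling(-n * log(epsilon) / .LN2SQ)
}

#' Number of hash functions for a filter of M bits holding n elements
#'
#' The count is \eqn{k = \mathrm{round}((M/n)\ln 2)} clamped to
#' \code{[8, 64]}. The unclamped value is the textbook optimum for a Bloom
#' filter of `M` bits and `n` elements; the clamp keeps the number of probes
#' bounded on both sides. Any filter sized by [requiredBits()] at
#' `epsilon = 0.005` uses exactly 8 hash functions (the optimum, 7.64,
#' rounds and clamps to 8).
#'
#' @param M filter size in bits (>= 0).
#' @param n number of elements (>= 1).
#' @return integer hash-function count in \code{[8, 64]}.
#' @examples
#' numHashes(requiredBits(1e6, 0.005), 1e6)  # 8
#' @export
numHashes <- function(M, n) {
    stopifnot(is.numeric(M), is.numeric(n))
    if (any(n < 1)) stop("'n' must be at least 1")
    if (any(M < 0)) stop("'M' must be non-negative")
    as.integer(pmax(8, pmin(64, round((M / n) * log(2)))))
}

#' Theoretical false-positive rate of a Bloom filter
#'
#' The standard approximation \eqn{(1 - e^{-kn/M})^k} for a filter of `M`
#' bits and `k` hash functions after `n` insertions.
#'
#' @param M filter size in bits (>= 1).
#' @param k number of hash functions (>= 1).
#' @param n number of elements added (>= 0).
#' @return probability in \code{[0, 1]}; 0 when `n = 0`.
#' @examples
#' theoreticalFpr(requiredBits(5e4, 0.005), 8, 5e4)  # ~0.005
#' @export
theoreticalFpr <- function(M, k, n) {
    stopifnot(is.numeric(M), is.numeric(k), is.numeric(n))
    if (any(M < 1)) stop("'M' must be at least 1")
    if (any(k < 1)) stop("'k' must be at least 1")
    if (any(n < 0)) stop("'n' must be non-negative")
    (1 - exp(-k * n / M))^k
}

#' Construct a FilterSpec
#'
#' Either give `(n, epsilon)` and let the spec derive `M` and `k`, or give
#' `(M, n)` directly (then `epsilon` is back-computed from theory unless
#' supplied). `n = 0` with no `M` yields the degenerate empty spec
#' (`M = 0`).
#'
#' @param n expected element count.
#' @param epsilon target false-positive rate; defaults to 0.005 when `M` is
#'   absent, and to the theoretical rate of `(M, k, n)` when `M` is given.
#' @param M optional explicit filter size in bits.
#' @return a [FilterSpec-class].
#' @examples
#' FilterSpec(n = 5e4, epsilon = 0.005)
#' @export
FilterSpec <- function(n, epsilon = NULL, M = NULL) {
    if (is.null(M)) {
        if (is.null(epsilon)) epsilon <- 0.005
        M <- if (n == 0) 0 else requiredBits(n, epsilon)
    }
    k <- if (n >= 1) numHashes(M, n) else 8L
    if (is.null(epsilon))
        epsilon <- if (n >= 1 && M >= 1) theoreticalFpr(M, k, n) else NA_real_
    new("FilterSpec", n = as.numeric(n), epsilon = as.numeric(epsilon),
        M = as.numeric(M), k = k)
}

#' Construct a HashScheme
#'
#' @param name `"fnv"`, `"md5"`, `"md4"` (alias of md5), or a fingerprint
#'   pair written `"fp:<kindA>+<kindB>"` with kinds out of `"maccs"`,
#'   `"morgan"`, `"atompair"`, `"path"` (e.g. `"fp:maccs+morgan"`).
#' @param nbits fold width for atom-pair fingerprints (default 2048); MACCS,
#'   Morgan/ECFP4 and path fingerprints use their backend's native widths.
#' @return a [HashScheme-class].
#' @examples
#' HashScheme("fnv")
#' HashScheme("fp:maccs+morgan")
#' @export
HashScheme <- function(name, nbits = 2048) {
    if (is(name, "HashScheme")) return(name)
    stopifnot(is.character(name), length(name) == 1L)
    if (startsWith(name, "fp:")) {
        body <- sub("^fp:", "", name)
        parts <- strsplit(body, ":", fixed = TRUE)[[1L]]
        kinds <- strsplit(parts[1L], "+", fixed = TRUE)[[1L]]
        if (length(parts) > 1L) nbits <- as.numeric(parts[2L])
        new("HashScheme", name = "fp",
            parameters = list(kinds = kinds, nbits = as.numeric(nbits)))
    } else if (name %in% .STRING_SCHEMES) {
        new("HashScheme", name = name, parameters = list())
    } else {
        stop("unknown hashing scheme: ", name)
    }
}

#' @describeIn HashScheme canonical serialized label, e.g.
#'   `"fp:maccs+morgan:2048"`; the label stored in filter files.
#' @param x a HashScheme.
#' @export
setMethod("schemeLabel", "HashScheme", function(x) {
    if (x@name == "fp")
        sprintf("fp:%s:%d", paste(x@parameters$kinds, collapse = "+"),
                as.integer(x@parameters$nbits))
    else x@name
})

#' Construct an empty Bloom filter
#'
#' @param n design capacity (expected number of elements).
#' @param epsilon target false-positive rate (default 0.005 when `M` is
#'   absent).
#' @param M optional explicit size in bits (overrides `epsilon` sizing).
#' @param scheme hashing scheme name or [HashScheme-class] (default FNV-1a
#'   string hashing).
#' @param canonicalize whether elements are SMILES to canonicalize before
#'   hashing (default TRUE for molecule filters; set FALSE for raw byte
#'   strings or pre-canonicalized corpora).
#' @return an all-zero [BloomFilter-class].
#' @examples
#' f <- BloomFilter(n = 1000, epsilon = 0.005, canonicalize = FALSE)
#' f <- bloomAdd(f, c("CCO", "c1ccccc1"))
#' bloomContains(f, c("CCO", "CCN"))
#' @export
BloomFilter <- function(n, epsilon = NULL, M = NULL, scheme = "fnv",
                        canonicalize = TRUE) {
    spec <- FilterSpec(n = n, epsilon = epsilon, M = M)
    if (spec@M < 1) stop("a buildable filter needs M >= 1 (n >= 1)")
    new("BloomFilter", spec = spec, scheme = HashScheme(scheme),
        bits = raw(ceiling(spec@M / 8)), countAdded = 0,
        canonicalized = isTRUE(canonicalize), metadata = list())
}

## ---- accessors -------------------------------------------------------

#' @describeIn BloomFilter the [FilterSpec-class] of a filter.
#' @param x a BloomFilter.
#' @export
setMethod("filterSpec", "BloomFilter", function(x) x@spec)

#' @describeIn BloomFilter the [HashScheme-class] of a filter.
#' @export
setMethod("hashScheme", "BloomFilter", function(x) x@scheme)

#' @describeIn BloomFilter filter length M in bits.
#' @export
setMethod("filterSize", "BloomFilter", function(x) x@spec@M)

#' @export
setMethod("filterSize", "FilterSpec", function(x) x@M)

#' @describeIn BloomFilter number of hash functions k.
#' @export
setMethod("numHashFunctions", "BloomFilter", function(x) x@spec@k)

#' @export
setMethod("numHashFunctions", "FilterSpec", function(x) x@k)

#' @describeIn BloomFilter design capacity n.
#' @export
setMethod("designCapacity", "BloomFilter", function(x) x@spec@n)

#' @export
setMethod("designCapacity", "FilterSpec", function(x) x@n)

#' @describeIn BloomFilter target false-positive rate epsilon.
#' @export
setMethod("targetFpr", "BloomFilter", function(x) x@spec@epsilon)

#' @export
setMethod("targetFpr", "FilterSpec", function(x) x@epsilon)

#' @describeIn BloomFilter number of add operations applied.
#' @export
setMethod("countAdded", "BloomFilter", function(x) x@countAdded)

#' @describeIn BloomFilter the raw bit payload (LSB-first packing).
#' @export
setMethod("filterBits", "BloomFilter", function(x) x@bits)

#' @describeIn BloomFilter whether SMILES are canonicalized before hashing.
#' @export
setMethod("isCanonicalizing", "BloomFilter", function(x) x@canonicalized)

#' @importFrom S4Vectors metadata
#' @export
setMethod("metadata", "BloomFilter", function(x, ...) x@metadata)

## ---- double hashing --------------------------------------------------

#' Construct a HashPair from two 64-bit values
#'
#' Accepts 8-byte big-endian raw vectors or non-negative numerics below
#' 2^53. A zero `hBeta` is replaced by 1 (the double-hashing restriction
#' \eqn{h_\beta \neq 0}).
#'
#' @param hAlpha,hBeta raw(8) or numeric(1).
#' @return a [HashPair-class].
#' @examples
#' hashIndices(HashPair(3, 5), k = 3, M = 7)  # 3 1 6
#' @export
HashPair <- function(hAlpha, hBeta) {
    a <- .asU64raw(hAlpha)
    b <- .asU64raw(hBeta)
    if (all(b == as.raw(0))) b <- .asU64raw(1)
    new("HashPair", hAlpha = a, hBeta = b)
}

.asU64raw <- function(v) {
    if (is.raw(v)) {
        stopifnot(length(v) == 8L)
        return(v)
    }
    stopifnot(is.numeric(v), length(v) == 1L, v >= 0, v < 2^53)
    out <- raw(8)
    x <- v
    for (i in 8:1) {
        out[i] <- as.raw(x %% 256)
        x <- x %/% 256
    }
    out
}

.u64hex <- function(r) {
    n <- length(r) / 8
    vapply(seq_len(n), function(i)
        paste(format(r[(8 * i - 7):(8 * i)]), collapse = ""), character(1))
}

#' Bit positions of an element under double hashing
#'
#' Expands a [HashPair-class] into the k probe positions
#' \eqn{h_i = (h_\alpha + i h_\beta) \bmod M}, i = 0..k-1, with the sum
#' taken modulo 2^64 before reduction. The first index is always
#' \eqn{h_\alpha \bmod M}.
#'
#' @param pair a [HashPair-class].
#' @param k number of indices (>= 1).
#' @param M filter size in bits (>= 1).
#' @return numeric vector of k positions in \code{[0, M)}.
#' @export
hashIndices <- function(pair, k, M) {
    stopifnot(is(pair, "HashPair"))
    if (M < 1) stop("'M' must be at least 1")
    if (k < 1) stop("'k' must be at least 1")
    cpp_hash_indices(pair@hAlpha, pair@hBeta, as.integer(k), as.numeric(M))
}

## ---- add / query -----------------------------------------------------

#' Add elements to a Bloom filter
#'
#' Sets the k hashed bits of every element. Adding is idempotent on the bit
#' state; `countAdded` counts calls, not distinct elements. Exceeding the
#' design capacity only warns: the filter still works but its realized
#' false-positive rate will exceed the design target. Elements that fail
#' SMILES canonicalization (when the filter canonicalizes) are skipped with
#' a warning. Empty strings are hashable but flagged, since they usually
#' indicate an upstream parsing bug.
#'
#' @param x a [BloomFilter-class].
#' @param elements character vector of SMILES (or raw byte strings for
#'   non-canonicalizing string-scheme filters).
#' @param ... unused.
#' @return the updated filter.
#' @export
setMethod("bloomAdd", "BloomFilter", function(x, elements, ...) {
    stopifnot(is.character(elements))
    if (length(elements) == 0L) return(x)
    if (any(!nzchar(elements)))
        warning("adding empty-string element(s); ",
                "this usually signals an upstream parsing bug")
    h <- .elementHashes(x, elements, drop.invalid = TRUE)
    nuse <- length(h$alpha) / 8
    newCount <- x@countAdded + nuse
    if (x@countAdded <= x@spec@n && newCount > x@spec@n)
        warning(sprintf(
            "filter past design capacity (%g added > n = %g); realized FPR will exceed %g",
            newCount, x@spec@n, x@spec@epsilon))
    if (nuse > 0)
        x@bits <- cpp_bloom_set(x@bits, h$alpha, h$beta, x@spec@k, x@spec@M)
    x@countAdded <- newCount
    validObject(x)
    x
})

#' Query elements of a Bloom filter
#'
#' TRUE iff all k hashed bits are set: never FALSE for an added element, and
#' TRUE for a never-added element with probability about the design
#' false-positive rate. Elements that fail canonicalization (when the filter
#' canonicalizes) are reported FALSE with a warning: an unparseable SMILES
#' cannot have been added as a molecule.
#'
#' @param x a [BloomFilter-class].
#' @param elements character vector.
#' @param ... unused.
#' @return logical vector, one verdict per element.
#' @export
setMethod("bloomContains", "BloomFilter", function(x, elements, ...) {
    stopifnot(is.character(elements))
    if (length(elements) == 0L) return(logical(0))
    h <- .elementHashes(x, elements, drop.invalid = FALSE)
    out <- logical(length(elements))
    if (any(h$keep))
        out[h$keep] <- cpp_bloom_check(x@bits, h$alpha, h$beta,
                                       x@spec@k, x@spec@M)
    out
})

#' Union of two Bloom filters
#'
#' Bitwise OR of two filters built with identical spec (same M and k) and
#' hashing scheme; the result answers TRUE whenever either operand would.
#' Supports incremental corpus builds.
#'
#' @param x,y compatible [BloomFilter-class] objects.
#' @return the merged [BloomFilter-class].
#' @importFrom BiocGenerics union
#' @export
setMethod("union", signature("BloomFilter", "BloomFilter"), function(x, y) {
    if (x@spec@M != y@spec@M || x@spec@k != y@spec@k)
        stop("incompatible filters: M and k must match")
    if (schemeLabel(x@scheme) != schemeLabel(y@scheme) ||
        x@canonicalized != y@canonicalized)
        stop("incompatible filters: hashing schemes must match")
    x@bits <- x@bits | y@bits
    x@countAdded <- x@countAdded + y@countAdded
    x
})

## ---- show ------------------------------------------------------------

setMethod("show", "FilterSpec", function(object) {
    cat(sprintf(
        "FilterSpec: n = %g, epsilon = %g, M = %g bits (%.6g MB), k = %d\n",
        object@n, object@epsilon, object@M, object@M / 8 / 2^20, object@k))
})

setMethod("show", "HashScheme", function(object) {
    cat("HashScheme:", schemeLabel(object), "\n")
})

setMethod("show", "BloomFilter", function(object) {
    cat("BloomFilter\n")
    cat(sprintf("  scheme: %s%s\n", schemeLabel(object@scheme),
                if (object@canonicalized) " (canonicalizing)" else ""))
    cat(sprintf("  M = %g bits, k = %d, design n = %g (epsilon = %g)\n",
                object@spec@M, object@spec@k, object@spec@n,
                object@spec@epsilon))
    cat(sprintf("  added: %g; occupancy: %.3f%%\n", object@countAdded,
                100 * cpp_popcount(object@bits) / object@spec@M))
})

setMethod("show", "HashPair", function(object) {
    cat(sprintf("HashPair: h_alpha = 0x%s, h_beta = 0x%s\n",
                .u64hex(object@hAlpha), .u64hex(object@hBeta)))
})
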