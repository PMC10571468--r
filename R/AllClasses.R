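#' @import methods
#' @importFrom S4Vectors metadata
#' @useDynLib ChemBloom, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

.FP_KINDS <- c("maccs", "morgan", "atompair", "path")
.STRING_SCHEMES <- c("fnv", "md5", "md4")

#' Bloom filter design parameters
#'
#' A \code{FilterSpec} records the four quantities that determine a Bloom
#' filter's behaviour: the expected number of elements \code{n}, the target
#' false-positive rate \code{epsilon}, the filter length \code{M} in bits,
#' and the number of hash functions \code{k}. When constructed from
#' \code{(n, epsilon)} the length is \code{M = ceiling(-n ln(eps) / (ln 2)^2)}
#' and \code{k = round((M/n) ln 2)} clamped to \code{[8, 64]}.
#'
#' @slot n numeric(1), expected element count (>= 0).
#' @slot epsilon numeric(1), target false-positive rate in (0, 1); may be
#'   \code{NA} for a spec derived from an explicit \code{M}.
#' @slot M numeric(1), filter length in bits.
#' @slot k integer(1), number of hash functions, always in \code{[8, 64]}.
#' @seealso [FilterSpec()], [requiredBits()], [numHashes()]
#' @exportClass FilterSpec
setClass("FilterSpec",
    representation(n = "numeric", epsilon = "numeric", M = "numeric",
                   k = "integer"))

setValidity("FilterSpec", function(object) {
    msg <- character()
    if (length(object@n) != 1L || is.na(object@n) || object@n < 0)
        msg <- c(msg, "'n' must be a single non-negative number")
    if (length(object@epsilon) != 1L ||
        (!is.na(object@epsilon) &&
         (object@epsilon <= 0 || object@epsilon >= 1)))
        msg <- c(msg, "'epsilon' must lie in (0, 1)")
    if (length(object@M) != 1L || is.na(object@M) || object@M < 0 ||
        object@M != floor(object@M))
        msg <- c(msg, "'M' must be a single non-negative integer value")
    if (length(object@k) != 1L || is.na(object@k) ||
        object@k < 8L || object@k > 64L)
        msg <- c(msg, "'k' must lie in [8, 64]")
    if (length(object@M) == 1L && length(object@n) == 1L &&
        !is.na(object@M) && !is.na(object@n) &&
        object@M == 0 && object@n > 0)
        msg <- c(msg, "a buildable spec (n > 0) requires M >= 1")
    if (length(msg)) msg else TRUE
})

#' Hashing scheme descriptor
#'
#' Identifies how elements are mapped to the two universal hash values
#' \eqn{h_\alpha, h_\beta} of the double-hashing construction. String schemes
#' hash the UTF-8 bytes of the (canonical) SMILES: \code{"fnv"} uses FNV-1a
#' 64-bit under two offset bases, \code{"md5"} (and its alias \code{"md4"})
#' splits the 128-bit digest into two 64-bit halves. Fingerprint schemes
#' (\code{"fp"}) interpret two structure fingerprints of different kinds as
#' big-endian integers reduced mod 2^64.
#'
#' @slot name character(1), one of \code{"fnv"}, \code{"md5"}, \code{"md4"},
#'   \code{"fp"}.
#' @slot parameters named list; for \code{"fp"} schemes it holds
#'   \code{kinds} (two distinct fingerprint kinds out of \code{"maccs"},
#'   \code{"morgan"}, \code{"atompair"}, \code{"path"}) and \code{nbits}
#'   (fold width for atom-pair fingerprints).
#' @seealso [HashScheme()]
#' @exportClass HashScheme
setClass("HashScheme",
    representation(name = "character", parameters = "list"))

setValidity("HashScheme", function(object) {
    msg <- character()
    if (length(object@name) != 1L ||
        !object@name %in% c(.STRING_SCHEMES, "fp"))
        msg <- c(msg, sprintf("unknown scheme name; use one of %s",
                 paste(c(.STRING_SCHEMES, "fp"), collapse = ", ")))
    if (identical(object@name, "fp")) {
        kinds <- object@parameters$kinds
        if (length(kinds) != 2L || !all(kinds %in% .FP_KINDS))
            msg <- c(msg, "fp scheme needs two fingerprint kinds")
        else if (kinds[1L] == kinds[2L])
            msg <- c(msg, "fp scheme needs two *distinct* fingerprint kinds")
        nb <- object@parameters$nbits
        if (is.null(nb) || length(nb) != 1L || nb < 64)
            msg <- c(msg, "fp scheme needs 'nbits' >= 64")
    }
    if (length(msg)) msg else TRUE
})

#' Pair of 64-bit universal hash values
#'
#' The two base hashes \eqn{h_\alpha} and \eqn{h_\beta} from which the k bit
#' positions of an element are derived as
#' \eqn{h_i = (h_\alpha + i h_\beta) \bmod M}. Values are stored as 8-byte
#' big-endian raw vectors because R doubles cannot represent every unsigned
#' 64-bit integer exactly. \eqn{h_\beta} is never zero; constructors
#' substitute 1 when the raw hash is 0 or divisible by the filter size.
#'
#' @slot hAlpha raw(8), big-endian.
#' @slot hBeta raw(8), big-endian, nonzero.
#' @seealso [HashPair()], [hashIndices()], [stringHashPair()]
#' @exportClass HashPair
setClass("HashPair", representation(hAlpha = "raw", hBeta = "raw"))

setValidity("HashPair", function(object) {
    msg <- character()
    if (length(object@hAlpha) != 8L || length(object@hBeta) != 8L)
        msg <- c(msg, "hash values must be 8-byte raw vectors")
    else if (all(object@hBeta == as.raw(0)))
        msg <- c(msg, "hBeta must be nonzero")
    if (length(msg)) msg else TRUE
})

#' Bloom filter over molecules or byte strings
#'
#' An \code{M}-bit array plus its design spec and hashing scheme. Elements are
#' added with [bloomAdd()] and queried with [bloomContains()]; a query is
#' never falsely negative for an added element, and falsely positive with
#' probability about \code{targetFpr(x)} at design capacity. When
#' \code{canonicalized} is \code{TRUE}, SMILES are canonicalized before
#' hashing both at build and at query time.
#'
#' @slot spec a [FilterSpec-class].
#' @slot scheme a [HashScheme-class].
#' @slot bits raw vector of \code{ceiling(M/8)} bytes; bit \code{i} of the
#'   filter is bit \code{i mod 8} (LSB first) of byte \code{floor(i/8)}.
#' @slot countAdded numeric(1), number of add operations applied.
#' @slot canonicalized logical(1), whether elements are canonical SMILES.
#' @slot metadata list, free-form (e.g. the build report).
#' @seealso [BloomFilter()], [bloomAdd()], [bloomContains()],
#'   [writeBloomFilter()]
#' @exportClass BloomFilter
setClass("BloomFilter",
    representation(spec = "FilterSpec", scheme = "HashScheme", bits = "raw",
                   countAdded = "numeric", canonicalized = "logical",
                   metadata = "list"))

setValidity("BloomFilter", function(object) {
    msg <- character()
    M <- object@spec@M
    if (length(object@bits) != ceiling(M / 8))
        msg <- c(msg, "bit vector length must be ceiling(M/8) bytes")
    if (length(object@countAdded) != 1L || object@countAdded < 0)
        msg <- c(msg, "countAdded must be a single non-negative number")
    else if (cpp_popcount(object@bits) > object@countAdded * object@spec@k)
        msg <- c(msg, "more bits set than countAdded * k allows")
    if (length(object@canonicalized) != 1L || is.na(object@canonicalized))
        msg <- c(msg, "canonicalized must be TRUE or FALSE")
    if (length(msg)) msg else TRUE
})

#' False-positive-rate sweep report
#'
#' Result of measuring empirical false-positive rates of one hashing scheme
#' across several filter sizes under the fifty-fifty split protocol, together
#' with the theoretical rate \eqn{(1 - e^{-kn/M})^k} at each size.
#'
#' @slot scheme the [HashScheme-class] evaluated.
#' @slot sizes numeric, filter sizes M in bits (strictly increasing).
#' @slot empiricalFpr numeric, measured false-positive fraction per size.
#' @slot theoreticalFpr numeric, formula value per size.
#' @slot nBuild numeric(1), elements added per filter.
#' @slot nQuery numeric(1), disjoint elements queried per filter.
#' @slot seed numeric(1), RNG seed that fixed the shuffle/split.
#' @seealso [sizeSweep()], [fiftyFiftyFpr()]
#' @exportClass FprReport
setClass("FprReport",
    representation(scheme = "HashScheme", sizes = "numeric",
                   empiricalFpr = "numeric", theoreticalFpr = "numeric",
                   nBuild = "numeric", nQuery = "numeric", seed = "numeric"))

setValidity("FprReport", function(object) {
    msg <- character()
    ns <- length(object@sizes)
    if (length(object@empiricalFpr) != ns ||
        length(object@theoreticalFpr) != ns)
        msg <- c(msg, "per-size vectors must align with 'sizes'")
    if (ns > 1L && any(diff(object@sizes) <= 0))
        msg <- c(msg, "'sizes' must be strictly increasing")
    if (any(object@empiricalFpr < 0 | object@empiricalFpr > 1))
        msg <- c(msg, "empirical FPR values must lie in [0, 1]")
    if (length(object@nQuery) != 1L || object@nQuery <= 0)
        msg <- c(msg, "nQuery must be positive")
    if (length(msg)) msg else TRUE
})
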