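#' @include core-filter.R
NULL

## FNV-1a 64-bit offset bases. The alpha basis is the standard published
## constant. The beta basis is frozen as FNV-1a64 of the single byte 0xff
## under the standard basis. Two plain FNV-1a runs over the same bytes are
## unusable as a double-hashing pair whatever their bases or byte order:
## the trailing multiply by an odd prime leaves the low output bits
## XOR-linear in the input bytes' low bits, so h_alpha and h_beta agree on
## that linear structure (bit 0 of their XOR is constant) and, for an
## even-sized filter, half of every element's probes fall in one parity
## class, inflating the false-positive rate about four-fold. h_beta is
## therefore FNV-1a under the alternate basis, consuming the bytes
## back-to-front, passed through a bijective 64-bit avalanche finalizer
## (splitmix64) that destroys the shared linear structure.
.FNV_BASIS_ALPHA_HEX <- "cbf29ce484222325"
.FNV_BASIS_BETA_HEX  <- "af64724c8602eb6e"

.hex2raw <- function(h) {
    as.raw(strtoi(substring(h, seq(1, nchar(h), 2), seq(2, nchar(h), 2)),
                  base = 16L))
}

#' FNV-1a 64-bit offset bases used by the package
#'
#' @return named character(2) of 16-hex-digit constants: `alpha` is the
#'   standard FNV-1a 64-bit offset basis, `beta` the package's documented
#'   alternate basis for the second universal hash.
#' @export
fnvOffsetBases <- function() {
    c(alpha = .FNV_BASIS_ALPHA_HEX, beta = .FNV_BASIS_BETA_HEX)
}

#' FNV-1a 64-bit hash
#'
#' The Fowler-Noll-Vo 1a hash: starting from an offset basis, each byte is
#' XOR-ed in and the state multiplied by the FNV prime 1099511628211, all
#' modulo 2^64. Fast, non-cryptographic, with strong avalanche behaviour --
#' the workhorse string hash for molecule membership filters. Input strings
#' are UTF-8 encoded before hashing.
#'
#' @param x character vector.
#' @param offsetBasis 16-hex-digit string or raw(8); defaults to the
#'   standard basis (the empty string hashes to the basis itself).
#' @return character vector of 16-hex-digit hash values.
#' @examples
#' fnv1a64("")        # the offset basis
#' fnv1a64("foobar")  # "85944171f73967e8"
#' @export
fnv1a64 <- function(x, offsetBasis = fnvOffsetBases()[["alpha"]]) {
    stopifnot(is.character(x))
    basis <- if (is.raw(offsetBasis)) offsetBasis else .hex2raw(offsetBasis)
    .u64hex(cpp_fnv1a64(x, basis))
}

## Batch hash-pair computation for string schemes: returns list(alpha, beta)
## of 8-byte-per-element raw blocks. The h_beta restrictions depend on the
## filter size; when M is given they are enforced, otherwise the raw hashes
## are returned (size sweeps enforce per size).
.stringHashBatch <- function(x, scheme.name, M = NULL) {
    if (scheme.name == "fnv") {
        alpha <- cpp_fnv1a64(x, .hex2raw(.FNV_BASIS_ALPHA_HEX))
        beta <- cpp_mix64(cpp_fnv1a64(x, .hex2raw(.FNV_BASIS_BETA_HEX),
                                      reverse = TRUE))
    } else if (scheme.name %in% c("md5", "md4")) {
        d <- cpp_md5(x)  # 16 bytes per element: split big-endian halves
        idx <- rep(seq(0L, length.out = length(x)) * 16L, each = 8L)
        alpha <- d[idx + seq_len(8)]
        beta <- d[idx + 8L + seq_len(8)]
    } else {
        stop("unknown string hashing scheme: ", scheme.name)
    }
    if (!is.null(M)) beta <- cpp_enforce_beta(beta, M)
    list(alpha = alpha, beta = beta)
}

#' Derive the universal hash pair of a byte string
#'
#' Maps an element to its two 64-bit base hashes \eqn{(h_\alpha, h_\beta)}.
#' Under `"fnv"`, \eqn{h_\alpha} is FNV-1a 64-bit under the standard offset
#' basis; \eqn{h_\beta} is FNV-1a under the package's alternate basis,
#' consuming the bytes back-to-front, finished with a bijective 64-bit
#' avalanche mix (splitmix64) -- plain FNV pairs share an XOR-linear
#' low-bit structure that ruins double hashing, which the finalizer removes;
#' under `"md5"`/`"md4"` the element's 128-bit digest is split
#' into big-endian halves (first half \eqn{h_\alpha}, second \eqn{h_\beta}).
#' The double-hashing restrictions are then enforced for the given filter
#' size: if \eqn{h_\beta = 0} or \eqn{h_\beta \bmod M = 0}, \eqn{h_\beta}
#' is replaced by 1, which strides through every residue for any M.
#'
#' @param x character(1), the element (hashed as UTF-8 bytes; no
#'   canonicalization here).
#' @param scheme scheme name or [HashScheme-class] (string schemes only).
#' @param M filter size in bits (>= 1) for the divisibility restriction.
#' @return a [HashPair-class].
#' @examples
#' stringHashPair("CCO", "fnv", M = 1000)
#' @export
stringHashPair <- function(x, scheme = "fnv", M) {
    stopifnot(is.character(x), length(x) == 1L)
    scheme <- HashScheme(scheme)
    if (scheme@name == "fp")
        stop("fingerprint schemes hash molecules, not strings; see fpHashPair()")
    if (M < 1) stop("'M' must be at least 1")
    h <- .stringHashBatch(x, scheme@name, as.numeric(M))
    new("HashPair", hAlpha = h$alpha, hBeta = h$beta)
}

## Scheme dispatcher used by bloomAdd / bloomContains. Returns
## list(alpha, beta, keep): raw hash blocks for the usable elements and a
## logical marking which input elements they correspond to.
.elementHashes <- function(filter, elements, drop.invalid = TRUE) {
    keep <- rep(TRUE, length(elements))
    if (filter@canonicalized) {
        cm <- canonicalizeSmiles(elements)
        keep <- cm$valid
        if (any(!keep))
            warning(sum(!keep), " element(s) failed SMILES parsing and were ",
                    if (drop.invalid) "skipped" else "reported absent")
        elements <- cm$canonicalSmiles[keep]
    }
    if (filter@scheme@name == "fp") {
        if (!filter@canonicalized) {
            ## fingerprints are functions of the molecular graph; parse even
            ## when the filter is not canonicalizing
            cm <- canonicalizeSmiles(elements)
            if (any(!cm$valid)) {
                warning(sum(!cm$valid), " element(s) failed SMILES parsing")
                keep[keep] <- cm$valid
                elements <- elements[cm$valid]
            }
        }
        kinds <- filter@scheme@parameters$kinds
        nbits <- filter@scheme@parameters$nbits
        if (length(elements)) {
            fpA <- moleculeFingerprints(elements, kinds[1L], nbits = nbits)
            fpB <- moleculeFingerprints(elements, kinds[2L], nbits = nbits)
            h <- .fpHashBatch(fpA, fpB, filter@spec@M)
        } else h <- list(alpha = raw(0), beta = raw(0))
    } else {
        h <- if (length(elements))
            .stringHashBatch(elements, filter@scheme@name, filter@spec@M)
        else list(alpha = raw(0), beta = raw(0))
    }
    list(alpha = h$alpha, beta = h$beta, keep = keep)
}

#' Avalanche score of a hashing scheme
#'
#' Monte-Carlo estimate of the avalanche effect: over `samples` random
#' strings, one randomly chosen character is replaced and the Hamming
#' distance between the \eqn{h_\alpha} values of the original and perturbed
#' strings is recorded. A well-mixed 64-bit hash flips about half of its
#' output bits (score near 0.5); structure-preserving maps score far lower.
#' `scheme = "identity"` is a deliberate non-avalanching test double that
#' reads the first 8 bytes of the string as the hash.
#'
#' @param scheme `"fnv"`, `"md5"`, `"md4"`, or `"identity"`.
#' @param samples number of perturbation pairs (>= 100).
#' @param seed RNG seed; equal seeds give identical scores.
#' @return mean fraction of flipped output bits, in \code{[0, 1]}.
#' @examples
#' avalancheScore("fnv", samples = 1000, seed = 1)  # ~0.5
#' @export
avalancheScore <- function(scheme, samples = 10000, seed = 1) {
    stopifnot(samples >= 100)
    pool <- c(LETTERS, letters, 0:9)
    withSeed(seed, {
        len <- sample(8:40, samples, replace = TRUE)
        orig <- vapply(len, function(l)
            paste(sample(pool, l, replace = TRUE), collapse = ""),
            character(1))
        pos <- vapply(len, function(l) sample.int(l, 1L), integer(1))
        repl <- sample(pool, samples, replace = TRUE)
        pert <- orig
        substr(pert, pos, pos) <- repl
        same <- substr(orig, pos, pos) == repl
        ## guarantee a real single-character change
        while (any(same)) {
            repl[same] <- sample(pool, sum(same), replace = TRUE)
            substr(pert, pos, pos) <- repl
            same <- substr(orig, pos, pos) == repl
        }
    })
    hash <- function(s) {
        if (identical(scheme, "identity")) {
            padded <- vapply(s, function(z)
                substr(paste0(z, strrep("\1", 8)), 1, 8), character(1),
                USE.NAMES = FALSE)
            unlist(lapply(padded, function(z)
                {v <- charToRaw(z); length(v) <- 8L; v}))
        } else {
            .stringHashBatch(s, HashScheme(scheme)@name, M = 2^31)$alpha
        }
    }
    mean(cpp_hamming64(hash(orig), hash(pert))) / 64
}

## Evaluate expr with a locally pinned RNG state, restoring the caller's.
withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
        get(".Random.seed", globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
             sample.kind = "Rejection")
    eval.parent(substitute(expr))
}
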