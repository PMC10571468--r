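#' @include evaluation.R
NULL

.VALENCE <- c(C = 4L, N = 3L, O = 2L, S = 2L, F = 1L, Cl = 1L, Br = 1L)

## sampling weights: organic molecules are carbon-dominated
.ELEMENT_W <- c(C = 10, N = 3, O = 3, S = 1, F = 1, Cl = 1, Br = 1)

## One random molecule as a SMILES string: seeded tree growth over a small
## organic-subset palette with explicit valence bookkeeping, optional double
## bonds and one optional ring closure. Constructed molecules always parse.
.randomSmiles <- function(natoms, palette) {
    val <- .VALENCE[palette]
    sym <- character(natoms)
    fv <- integer(natoms)
    parent <- integer(natoms)
    bond <- integer(natoms)  # order of the bond to parent
    grower <- palette[val[palette] >= 2L]
    wAll <- .ELEMENT_W[palette]
    wGrow <- .ELEMENT_W[grower]
    sym[1L] <- if (natoms == 1L) sample(palette, 1L, prob = wAll)
               else sample(grower, 1L, prob = wGrow)
    fv[1L] <- .VALENCE[[sym[1L]]]
    np <- 1L
    for (i in seq_len(natoms)[-1L]) {
        open <- which(fv[seq_len(np)] > 0L)
        if (!length(open)) break
        p <- open[sample.int(length(open), 1L)]
        ## keep at least one growth-capable atom while the tree is small
        el <- if (i < natoms && sum(fv[seq_len(np)]) <= 1L)
            sample(grower, 1L, prob = wGrow)
        else sample(palette, 1L, prob = wAll)
        ord <- if (fv[p] >= 2L && .VALENCE[[el]] >= 2L && runif(1) < 0.15)
            2L else 1L
        np <- np + 1L
        sym[np] <- el
        parent[np] <- p
        bond[np] <- ord
        fv[p] <- fv[p] - ord
        fv[np] <- .VALENCE[[el]] - ord
    }
    sym <- sym[seq_len(np)]; fv <- fv[seq_len(np)]
    parent <- parent[seq_len(np)]; bond <- bond[seq_len(np)]
    ## one ring closure between non-adjacent open atoms
    ring <- c(0L, 0L)
    if (np >= 5L && runif(1) < 0.25) {
        open <- which(fv > 0L)
        if (length(open) >= 2L) {
            a <- open[sample.int(length(open), 1L)]
            ok <- open[open != a & parent[open] != a & parent[a] != open]
            if (length(ok)) {
                b <- ok[sample.int(length(ok), 1L)]
                ring <- c(a, b)
            }
        }
    }
    kids <- split(seq_len(np)[-1L], parent[-1L])
    emit <- function(a) {
        tok <- sym[a]
        if (a %in% ring) tok <- paste0(tok, "1")
        ch <- kids[[as.character(a)]]
        if (!is.null(ch)) {
            sub <- vapply(ch, function(cc)
                paste0(if (bond[cc] == 2L) "=" else "", emit(cc)),
                character(1))
            nc <- length(sub)
            if (nc > 1L)
                sub <- c(paste0("(", sub[-nc], ")"), sub[nc])
            tok <- paste0(tok, paste(sub, collapse = ""))
        }
        tok
    }
    emit(1L)
}

#' Deterministic synthetic corpus of molecules or byte strings
#'
#' Generates `n` unique records as a pure function of its arguments, so
#' every experiment runs without downloading a chemical library. In
#' `"smiles"` mode, valence-respecting branched/cyclic molecules over the
#' organic-subset palette are grown by a seeded random tree procedure,
#' canonicalized, and deduplicated in canonical-SMILES space until `n`
#' unique records exist -- uniqueness holds in the same space the filter
#' hashes. In `"bytes"` mode, random printable-ASCII strings of length
#' 10-80 are generated and deduplicated byte-wise.
#'
#' @param n number of records (>= 1).
#' @param seed RNG seed; equal arguments give identical corpora.
#' @param mode `"smiles"` or `"bytes"`.
#' @param maxHeavyAtoms largest molecule size in heavy atoms (smiles mode).
#' @param palette element symbols to draw from (smiles mode).
#' @return character vector of `n` unique records (canonical SMILES in
#'   smiles mode).
#' @examples
#' generateCorpus(5, seed = 7)
#' @importFrom stats runif
#' @export
generateCorpus <- function(n, seed = 1, mode = c("smiles", "bytes"),
                           maxHeavyAtoms = 12,
                           palette = c("C", "N", "O", "S", "F", "Cl", "Br")) {
    mode <- match.arg(mode)
    stopifnot(n >= 1)
    if (mode == "smiles") stopifnot(all(palette %in% names(.VALENCE)))
    out <- character(0)
    withSeed(seed, {
        for (round in seq_len(25L)) {
            need <- n - length(out)
            if (need <= 0L) break
            m <- ceiling(need * 1.4) + 50L
            if (mode == "bytes") {
                lens <- sample(10:80, m, replace = TRUE)
                chars <- sample(33:126, sum(lens), replace = TRUE)
                batch <- vapply(split(chars, rep(seq_len(m), lens)),
                                intToUtf8, character(1), USE.NAMES = FALSE)
            } else {
                sizes <- sample.int(maxHeavyAtoms, m, replace = TRUE)
                raw <- vapply(sizes, .randomSmiles, character(1),
                              palette = palette)
                cm <- canonicalizeSmiles(raw)
                batch <- unique(cm$canonicalSmiles[cm$valid])
            }
            out <- c(out, setdiff(unique(batch), out))
        }
    })
    if (length(out) < n)
        stop("could not reach ", n, " unique records; the bottleneck is ",
             if (mode == "smiles")
                 "'maxHeavyAtoms'/'palette' (chemical space too small)"
             else "the requested corpus size")
    out[seq_len(n)]
}

#' Family of closely related molecules
#'
#' Emits single-substitution variants of one linear scaffold: the base
#' all-carbon chain of `baseLength` heavy atoms plus variants with one
#' position replaced by N, O, or S, in seeded random order. Such homolog
#' series have highly similar structure fingerprints -- much more similar
#' than random molecule pairs -- which is what makes fingerprint-pair
#' hashing collide in a Bloom filter far more often than string hashing.
#'
#' @param baseLength heavy atoms in the scaffold chain (>= 3).
#' @param count number of molecules to return (>= 2). Chain symmetry makes
#'   position `p` equivalent to `baseLength + 1 - p`, so one scaffold has
#'   `3 * ceiling(baseLength / 2) + 1` distinct variants.
#' @param seed RNG seed.
#' @return character vector of `count` unique canonical SMILES.
#' @examples
#' homologSeries(baseLength = 6, count = 5, seed = 1)
#' @export
homologSeries <- function(baseLength = 6, count = 12, seed = 1) {
    stopifnot(baseLength >= 3, count >= 2)
    base <- strrep("C", baseLength)
    variants <- c(base, unlist(lapply(c("N", "O", "S"), function(el)
        vapply(seq_len(baseLength), function(p) {
            s <- strsplit(base, "")[[1L]]
            s[p] <- el
            paste(s, collapse = "")
        }, character(1)))))
    cm <- canonicalizeSmiles(variants)
    pool <- unique(cm$canonicalSmiles[cm$valid])
    if (count > length(pool))
        stop("only ", length(pool), " distinct variants exist for ",
             "baseLength = ", baseLength, "; increase it or lower 'count'")
    withSeed(seed, sample(pool, count))
}
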