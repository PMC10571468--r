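#' @include hashing.R
NULL

#' Canonicalize SMILES strings
#'
#' Normalizes each SMILES to the chemistry backend's canonical (isomeric)
#' form, so that any two spellings of one molecule compare equal as strings.
#' Canonicalization is idempotent. Unparseable inputs are flagged rather
#' than raising: `valid = FALSE` with the input left unmodified.
#'
#' @param smiles character vector of SMILES strings.
#' @param stripStereo if TRUE, stereo bond marks (`/`, `\\`), chirality tags
#'   (`@`) and isotope labels are removed from the input before
#'   canonicalization, collapsing stereoisomers to one record.
#' @return a [S4Vectors::DataFrame] with columns `inputSmiles`,
#'   `canonicalSmiles` and `valid`; the number of invalid records is
#'   attached as `metadata(x)$nInvalid`.
#' @examples
#' cm <- canonicalizeSmiles(c("OCC", "C(O)C", "not_a_smiles("))
#' cm$canonicalSmiles[1] == cm$canonicalSmiles[2]  # TRUE: same molecule
#' cm$valid                                        # TRUE TRUE FALSE
#' @importFrom S4Vectors DataFrame metadata<-
#' @export
canonicalizeSmiles <- function(smiles, stripStereo = FALSE) {
    stopifnot(is.character(smiles))
    n <- length(smiles)
    out <- DataFrame(inputSmiles = smiles,
                     canonicalSmiles = smiles,
                     valid = logical(n))
    ## a SMILES is a single whitespace-free token
    usable <- !is.na(smiles) & nzchar(smiles) & !grepl("[[:space:]]", smiles)
    if (any(usable)) {
        inp <- smiles[usable]
        if (stripStereo) {
            inp <- gsub("[/\\\\]", "", inp)
            inp <- gsub("@+", "", inp)
            inp <- gsub("\\[([0-9]+)", "[", inp)
        }
        txt <- paste0(inp, " x", seq_along(inp), "\n", collapse = "")
        res <- ChemmineOB::convertFormat(
            "SMI", "CAN", txt, options = data.frame(names = "e", args = ""))
        lines <- strsplit(res, "\n", fixed = TRUE)[[1L]]
        parts <- strsplit(lines, "\t", fixed = TRUE)
        ids <- as.integer(sub("^x", "", vapply(parts, `[`, "", 2L)))
        can <- vapply(parts, `[`, "", 1L)
        ok <- !is.na(ids) & nzchar(can)
        map <- which(usable)[ids[ok]]
        out$canonicalSmiles[map] <- can[ok]
        out$valid[map] <- TRUE
    }
    metadata(out)$nInvalid <- sum(!out$valid)
    out
}

.FP_BACKEND <- c(maccs = "MACCS", morgan = "ECFP4", path = "FP2")

#' Structure fingerprints of molecules
#'
#' Computes fixed-length binary fingerprints: `"maccs"` (166 structural
#' keys, 168-bit frame), `"morgan"` (circular/ECFP4, radius 2, 4096 bits),
#' `"path"` (linear-fragment/path fingerprint, 1024-bit frame) -- all at
#' their backend's native widths -- and `"atompair"` (atom-pair descriptors
#' folded to `nbits` positions by code mod `nbits`). Fingerprints are
#' functions of the molecular graph: two SMILES spellings of one molecule
#' give identical bit vectors. All inputs must be valid SMILES
#' (canonicalize first and filter on `valid`); an unparseable input is a
#' precondition error. The MACCS/ECFP/path kinds run through the OpenBabel
#' batch fingerprinter, which handles corpus-scale input in seconds.
#'
#' @param smiles character vector of valid SMILES.
#' @param kind one of `"maccs"`, `"morgan"`, `"atompair"`, `"path"`.
#' @param nbits fold width for `"atompair"` (default 2048); ignored for the
#'   fixed-width kinds.
#' @return integer 0/1 matrix, one row per molecule, with attribute `kind`.
#' @examples
#' fp <- moleculeFingerprints(c("CCO", "c1ccccc1"), "maccs")
#' dim(fp)
#' @export
moleculeFingerprints <- function(smiles,
                                 kind = c("maccs", "morgan", "atompair",
                                          "path"),
                                 nbits = 2048) {
    kind <- match.arg(kind)
    stopifnot(is.character(smiles), length(smiles) >= 1L)
    fp <- if (kind == "atompair") .atomPairFolded(smiles, nbits)
          else .obabelFps(smiles, .FP_BACKEND[[kind]])
    structure(fp, kind = kind)
}

## Batch fingerprints through the OpenBabel command-line fingerprinter
## (FPS output: one hex bit string per molecule, id column preserved).
.obabelFps <- function(smiles, fpName) {
    if (Sys.which("obabel") == "")
        stop("the 'obabel' executable is required for ", fpName,
             " fingerprints but was not found on PATH")
    fin <- tempfile(fileext = ".smi")
    fout <- tempfile(fileext = ".fps")
    on.exit(unlink(c(fin, fout)))
    writeLines(paste(smiles, paste0("x", seq_along(smiles))), fin)
    status <- suppressWarnings(
        system2("obabel", c("-ismi", fin, "-ofps", paste0("-xf", fpName),
                            "-O", fout, "-e"),
                stdout = FALSE, stderr = FALSE))
    if (status != 0 || !file.exists(fout))
        stop("OpenBabel fingerprinting failed (status ", status, ")")
    lines <- readLines(fout, warn = FALSE)
    lines <- lines[!startsWith(lines, "#")]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    ids <- as.integer(sub("^x", "", vapply(parts, `[`, "", 2L)))
    hex <- vapply(parts, `[`, "", 1L)
    if (anyNA(ids) || length(ids) != length(smiles))
        stop("fingerprinting requires valid SMILES: ",
             length(smiles) - sum(!is.na(ids)),
             " input(s) failed to parse")
    fp <- cpp_hex_to_bits(hex)
    fp[order(ids), , drop = FALSE]
}

## Atom-pair descriptors via ChemmineR, folded to a fixed width: descriptor
## code c sets bit (c mod nbits). Folding keeps small synthetic molecules
## informative, unlike a fixed reference-descriptor basis.
.atomPairFolded <- function(smiles, nbits) {
    nbits <- as.integer(nbits)
    sdf <- tryCatch(
        suppressWarnings(ChemmineR::smiles2sdf(smiles)),
        error = function(e) stop(
            "fingerprinting requires valid SMILES (backend: ",
            conditionMessage(e), ")", call. = FALSE))
    if (length(sdf) != length(smiles))
        stop("fingerprinting requires valid SMILES: ",
             length(smiles) - length(sdf), " input(s) failed to parse")
    ChemmineR::cid(sdf) <- paste0("x", seq_along(smiles))
    apset <- suppressWarnings(ChemmineR::sdf2ap(sdf))
    codes <- ChemmineR::ap(apset)
    fp <- matrix(0L, nrow = length(smiles), ncol = nbits)
    for (i in seq_along(codes)) {
        cc <- codes[[i]]
        if (length(cc) && !(length(cc) == 1L && cc[1L] == 0))
            fp[i, unique(cc %% nbits) + 1L] <- 1L
    }
    fp
}

## Batch fingerprint-pair hashing: big-endian integer value of each row
## reduced mod 2^64, beta restrictions enforced for M.
.fpHashBatch <- function(fpA, fpB, M) {
    list(alpha = cpp_fp_to_u64(fpA),
         beta = cpp_enforce_beta(cpp_fp_to_u64(fpB), M))
}

#' Hash pair from two structure fingerprints
#'
#' Interprets each fingerprint's bit vector as a big-endian unsigned integer
#' reduced mod 2^64 -- deliberately *without* re-hashing, which preserves the
#' structure-correlated, non-avalanching character of fingerprints (similar
#' molecules give similar fingerprints, hence clustered filter indices).
#' The two fingerprints must be of different kinds; the \eqn{h_\beta}
#' restrictions and fallback of [stringHashPair()] are then applied.
#'
#' @param fpAlpha,fpBeta fingerprint vectors or single-row matrices from
#'   [moleculeFingerprints()], of two distinct kinds.
#' @param M filter size in bits (>= 1).
#' @return a [HashPair-class].
#' @export
fpHashPair <- function(fpAlpha, fpBeta, M) {
    if (M < 1) stop("'M' must be at least 1")
    ka <- attr(fpAlpha, "kind"); kb <- attr(fpBeta, "kind")
    if (!is.null(ka) && !is.null(kb) && identical(ka, kb))
        stop("the two fingerprints must be of distinct kinds")
    toMat <- function(v) {
        if (is.matrix(v)) {
            stopifnot(nrow(v) == 1L)
            m <- v
        } else m <- matrix(as.integer(v), nrow = 1L)
        storage.mode(m) <- "integer"
        m
    }
    h <- .fpHashBatch(toMat(fpAlpha), toMat(fpBeta), as.numeric(M))
    if (all(h$beta == as.raw(0))) h$beta <- .asU64raw(1)
    new("HashPair", hAlpha = h$alpha, hBeta = h$beta)
}

#' Read a SMILES line file
#'
#' One record per line: the molecule as the first whitespace-separated
#' token, an optional identifier as the second. Blank lines and lines
#' starting with `#` are ignored.
#'
#' @param path file path.
#' @return data.frame with columns `smiles` and `id` (NA where absent).
#' @export
readSmilesFile <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    toks <- strsplit(lines, "[[:space:]]+")
    data.frame(smiles = vapply(toks, `[`, "", 1L),
               id = vapply(toks, `[`, "", 2L))
}
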