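#' @include chem.R
NULL

## On-disk format, version 1. Little-endian integers throughout; bit i of
## the filter is bit (i mod 8), LSB-first, of payload byte floor(i/8).
##
##   offset  size  field
##   0       4     magic "CBLM"
##   4       4     format version (uint32) = 1
##   8       8     M, filter length in bits (uint64)
##   16      4     k, hash count (uint32)
##   20      8     n, design capacity (uint64)
##   28      8     count of add operations (uint64)
##   36      8     design epsilon (IEEE-754 double)
##   44      1     canonicalized flag (uint8)
##   45      2     scheme label length L (uint16)
##   47      L     scheme label, UTF-8 (e.g. "fnv", "fp:maccs+morgan:2048")
##   47+L    ceil(M/8)  bit payload
.FILTER_MAGIC <- charToRaw("CBLM")
.FORMAT_VERSION <- 1

.packUint <- function(x, nbytes) {
    stopifnot(x >= 0, x < 2^53)
    out <- raw(nbytes)
    for (i in seq_len(nbytes)) {
        out[i] <- as.raw(x %% 256)
        x <- x %/% 256
    }
    if (x != 0) stop("value too large for field")
    out
}

.unpackUint <- function(r) {
    sum(as.numeric(r) * 256^(seq_along(r) - 1))
}

#' Write a Bloom filter to its portable on-disk format
#'
#' The format is platform-independent (fixed endianness and bit order), so
#' a filter built once can ship to any machine: a purchasability filter for
#' millions of molecules is a few MB. See the format table in the package
#' source for the byte layout.
#'
#' @param filter a [BloomFilter-class].
#' @param path destination file path.
#' @return number of bytes written, invisibly.
#' @seealso [readBloomFilter()]
#' @export
writeBloomFilter <- function(filter, path) {
    stopifnot(is(filter, "BloomFilter"))
    label <- schemeLabel(filter@scheme)
    lab <- charToRaw(enc2utf8(label))
    header <- c(.FILTER_MAGIC,
                .packUint(.FORMAT_VERSION, 4L),
                .packUint(filter@spec@M, 8L),
                .packUint(filter@spec@k, 4L),
                .packUint(filter@spec@n, 8L),
                .packUint(filter@countAdded, 8L),
                writeBin(as.numeric(filter@spec@epsilon), raw(),
                         size = 8L, endian = "little"),
                as.raw(as.integer(filter@canonicalized)),
                .packUint(length(lab), 2L),
                lab)
    con <- tryCatch(file(path, "wb"),
                    error = function(e) stop("cannot write filter to '",
                                             path, "': ",
                                             conditionMessage(e),
                                             call. = FALSE))
    on.exit(close(con))
    writeBin(header, con)
    writeBin(filter@bits, con)
    invisible(as.numeric(length(header) + length(filter@bits)))
}

#' Read a Bloom filter from disk
#'
#' Reconstructs the filter, its spec and its hashing scheme. Files with a
#' wrong magic tag or an unsupported format version are rejected, a payload
#' whose length disagrees with the header is a corruption error, and an
#' unknown scheme label is an incompatibility error.
#'
#' @param path a file written by [writeBloomFilter()].
#' @return a [BloomFilter-class].
#' @export
readBloomFilter <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    blob <- readBin(path, "raw", n = file.size(path))
    if (length(blob) < 47L || !identical(blob[1:4], .FILTER_MAGIC))
        stop("not a Bloom filter file (bad magic): ", path)
    version <- .unpackUint(blob[5:8])
    if (version != .FORMAT_VERSION)
        stop("unsupported filter format version ", version)
    M <- .unpackUint(blob[9:16])
    k <- .unpackUint(blob[17:20])
    n <- .unpackUint(blob[21:28])
    added <- .unpackUint(blob[29:36])
    epsilon <- readBin(blob[37:44], "numeric", size = 8L, endian = "little")
    canonicalized <- as.logical(as.integer(blob[45]))
    labLen <- .unpackUint(blob[46:47])
    if (length(blob) < 47L + labLen)
        stop("corrupt filter file (truncated header): ", path)
    label <- rawToChar(blob[47L + seq_len(labLen)])
    payload <- blob[-seq_len(47L + labLen)]
    if (length(payload) != ceiling(M / 8))
        stop("corrupt filter file: payload is ", length(payload),
             " bytes, header requires ", ceiling(M / 8))
    scheme <- HashScheme(label)  # unknown label -> incompatibility error
    spec <- new("FilterSpec", n = n, epsilon = epsilon, M = M,
                k = as.integer(k))
    new("BloomFilter", spec = spec, scheme = scheme, bits = payload,
        countAdded = added, canonicalized = canonicalized,
        metadata = list(source = path))
}

#' Build a Bloom filter from a SMILES file
#'
#' Two-pass bulk construction: the file's usable records are counted (and,
#' when `canonicalize = TRUE`, canonicalized, with unparseable records
#' skipped and counted), the filter is sized from that count via
#' [requiredBits()] and [numHashes()] so `epsilon` drives the size exactly,
#' and every usable record is added. Supplying `n` switches to single-pass
#' sizing from the estimate instead of the counted total. The resolved
#' design (n, epsilon, M, k) is logged before any element is added, and the
#' build report (records read, invalid skipped, M, k, throughput) is stored
#' in `metadata(filter)$buildReport`.
#'
#' @param path SMILES line file (see [readSmilesFile()]).
#' @param epsilon target false-positive rate (default 0.005).
#' @param scheme hashing scheme name or [HashScheme-class].
#' @param canonicalize canonicalize records before hashing (default TRUE).
#' @param n optional capacity estimate for single-pass sizing.
#' @return a [BloomFilter-class] containing every usable record.
#' @export
buildFromSmiles <- function(path, epsilon = 0.005, scheme = "fnv",
                            canonicalize = TRUE, n = NULL) {
    records <- readSmilesFile(path)
    nRead <- nrow(records)
    if (canonicalize) {
        cm <- canonicalizeSmiles(records$smiles)
        valid <- cm$valid
        elements <- cm$canonicalSmiles[valid]
    } else {
        valid <- !is.na(records$smiles) & nzchar(records$smiles)
        elements <- records$smiles[valid]
    }
    nInvalid <- sum(!valid)
    if (nInvalid > 0)
        warning(nInvalid, " of ", nRead,
                " record(s) were unusable and skipped")
    if (length(elements) == 0L)
        stop("no usable records in '", path, "'")
    capacity <- if (is.null(n)) length(elements) else n
    filter <- BloomFilter(n = capacity, epsilon = epsilon, M = NULL,
                          scheme = scheme, canonicalize = canonicalize)
    message(sprintf(
        "building filter: n = %g, epsilon = %g, M = %g bits, k = %d, scheme = %s",
        capacity, epsilon, filter@spec@M, filter@spec@k,
        schemeLabel(filter@scheme)))
    t0 <- proc.time()[["elapsed"]]
    ## records are already canonical (or raw by request): hash them as-is
    h <- if (filter@scheme@name == "fp") {
        kinds <- filter@scheme@parameters$kinds
        nb <- filter@scheme@parameters$nbits
        .fpHashBatch(moleculeFingerprints(elements, kinds[1L], nbits = nb),
                     moleculeFingerprints(elements, kinds[2L], nbits = nb),
                     filter@spec@M)
    } else {
        .stringHashBatch(elements, filter@scheme@name, filter@spec@M)
    }
    filter@bits <- cpp_bloom_set(filter@bits, h$alpha, h$beta,
                                 filter@spec@k, filter@spec@M)
    filter@countAdded <- length(elements)
    elapsed <- proc.time()[["elapsed"]] - t0
    message(sprintf("added %d element(s) in %.2fs (%.3g elements/s)",
                    length(elements), elapsed,
                    length(elements) / max(elapsed, 1e-9)))
    filter@metadata$buildReport <- list(
        recordsRead = nRead, invalidSkipped = nInvalid,
        added = length(elements), M = filter@spec@M, k = filter@spec@k,
        epsilon = epsilon, elapsedSec = elapsed,
        throughput = length(elements) / max(elapsed, 1e-9))
    validObject(filter)
    filter
}
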