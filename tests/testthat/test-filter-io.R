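test_that("save/load round-trips filters bit-exactly", {
    strs <- unique(randomStrings(500, seed = 7))
    f <- bloomAdd(BloomFilter(n = 500, canonicalize = FALSE), strs)
    path <- tempfile(fileext = ".bloom")
    nb <- writeBloomFilter(f, path)
    expect_identical(nb, file.size(path))
    g <- readBloomFilter(path)
    expect_identical(filterBits(g), filterBits(f))
    expect_identical(filterSize(g), filterSize(f))
    expect_identical(numHashFunctions(g), numHashFunctions(f))
    expect_identical(countAdded(g), countAdded(f))
    expect_equal(targetFpr(g), targetFpr(f))
    expect_identical(schemeLabel(hashScheme(g)), schemeLabel(hashScheme(f)))
    expect_identical(isCanonicalizing(g), isCanonicalizing(f))
    ## identical verdicts on a thousand probes
    probes <- c(strs[1:500], randomStrings(500, seed = 8))
    expect_identical(bloomContains(g, probes), bloomContains(f, probes))
})

test_that("on-disk size is the fixed header plus ceiling(M/8) payload", {
    f <- BloomFilter(n = 8, M = 64, canonicalize = FALSE)
    path <- tempfile()
    writeBloomFilter(f, path)
    label <- schemeLabel(hashScheme(f))
    expect_identical(file.size(path), 47 + nchar(label) + 8)
    ## empty filter payload is all zero bytes
    blob <- readBin(path, "raw", n = file.size(path))
    payload <- blob[(47 + nchar(label) + 1):length(blob)]
    expect_identical(payload, raw(8))
})

test_that("corrupt or foreign files are rejected", {
    f <- bloomAdd(BloomFilter(n = 10, canonicalize = FALSE), "CCO")
    path <- tempfile()
    writeBloomFilter(f, path)
    ## flipped magic byte
    blob <- readBin(path, "raw", n = file.size(path))
    bad <- blob; bad[1] <- as.raw(255)
    p1 <- tempfile(); writeBin(bad, p1)
    expect_error(readBloomFilter(p1), "magic")
    ## unsupported version
    bad <- blob; bad[5] <- as.raw(99)
    p2 <- tempfile(); writeBin(bad, p2)
    expect_error(readBloomFilter(p2), "version")
    ## truncated payload
    p3 <- tempfile(); writeBin(blob[-length(blob)], p3)
    expect_error(readBloomFilter(p3), "corrupt")
    expect_error(readBloomFilter(tempfile()), "no such file")
})

test_that("fingerprint schemes round-trip through the scheme label", {
    f <- BloomFilter(n = 5, scheme = "fp:morgan+path")
    path <- tempfile()
    writeBloomFilter(f, path)
    g <- readBloomFilter(path)
    expect_identical(hashScheme(g)@parameters$kinds, c("morgan", "path"))
    expect_identical(hashScheme(g)@parameters$nbits, 2048)
})

test_that("buildFromSmiles sizes from the usable count and finds every record", {
    corpus <- fixtureCorpus(1000, seed = 41)
    path <- writeSmilesFixture(corpus, ids = paste0("m", seq_along(corpus)))
    f <- suppressMessages(buildFromSmiles(path, epsilon = 0.005))
    expect_identical(numHashFunctions(f), 8L)
    expect_identical(filterSize(f), requiredBits(1000, 0.005))
    expect_true(all(bloomContains(f, corpus)))
    rep <- metadata(f)$buildReport
    expect_identical(rep$recordsRead, 1000L)
    expect_identical(rep$invalidSkipped, 0L)
    expect_identical(rep$added, 1000L)
})

test_that("buildFromSmiles counts and skips invalid records", {
    good <- fixtureCorpus(200, seed = 43)[1:95]
    bad <- paste0("xx(", 1:5)
    path <- writeSmilesFixture(c(good, bad))
    expect_warning(
        f <- suppressMessages(buildFromSmiles(path)),
        "5 of 100")
    rep <- metadata(f)$buildReport
    expect_identical(rep$added, 95L)
    expect_identical(rep$invalidSkipped, 5L)
    ## a file with no usable records is a build error
    allBad <- writeSmilesFixture(bad)
    expect_error(
        suppressWarnings(suppressMessages(buildFromSmiles(allBad))),
        "no usable")
})

test_that("identical builds give bit-identical filters and files", {
    corpus <- fixtureCorpus(300, seed = 47)
    path <- writeSmilesFixture(corpus)
    f1 <- suppressMessages(buildFromSmiles(path))
    f2 <- suppressMessages(buildFromSmiles(path))
    expect_identical(filterBits(f1), filterBits(f2))
    p1 <- tempfile(); p2 <- tempfile()
    writeBloomFilter(f1, p1); writeBloomFilter(f2, p2)
    expect_identical(readBin(p1, "raw", file.size(p1)),
                     readBin(p2, "raw", file.size(p2)))
})

test_that("single-pass builds size from the supplied estimate", {
    corpus <- fixtureCorpus(200, seed = 53)
    path <- writeSmilesFixture(corpus)
    f <- suppressWarnings(suppressMessages(
        buildFromSmiles(path, n = 500)))
    expect_identical(filterSize(f), requiredBits(500, 0.005))
    expect_identical(designCapacity(f), 500)
    expect_true(all(bloomContains(f, corpus)))
})
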