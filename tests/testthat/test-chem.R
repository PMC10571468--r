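test_that("canonicalization unifies spellings and flags bad input", {
    cm <- canonicalizeSmiles(c("OCC", "C(O)C", "not_a_smiles(", "c1ccccc1"))
    expect_identical(cm$valid, c(TRUE, TRUE, FALSE, TRUE))
    ## two spellings of ethanol agree (equality, not a specific string)
    expect_identical(cm$canonicalSmiles[1], cm$canonicalSmiles[2])
    ## invalid input is passed through unmodified
    expect_identical(cm$canonicalSmiles[3], "not_a_smiles(")
    expect_identical(S4Vectors::metadata(cm)$nInvalid, 1L)
    ## whitespace, empties and NA are not SMILES
    cm2 <- canonicalizeSmiles(c("C C", "", NA_character_))
    expect_false(any(cm2$valid))
})

test_that("canonicalization is idempotent on a synthetic corpus", {
    corpus <- fixtureCorpus(1000, seed = 19)
    again <- canonicalizeSmiles(corpus)
    expect_true(all(again$valid))
    expect_identical(again$canonicalSmiles, corpus)
})

test_that("stereo stripping collapses stereoisomers", {
    iso <- c("C[C@H](N)C(=O)O", "C[C@@H](N)C(=O)O")
    keep <- canonicalizeSmiles(iso)
    expect_false(keep$canonicalSmiles[1] == keep$canonicalSmiles[2])
    strip <- canonicalizeSmiles(iso, stripStereo = TRUE)
    expect_identical(strip$canonicalSmiles[1], strip$canonicalSmiles[2])
})

test_that("fingerprints are graph functions at fixed widths", {
    two <- canonicalizeSmiles(c("OCC", "C(O)C"))$canonicalSmiles
    widths <- c(maccs = 168L, morgan = 4096L, path = 1024L,
                atompair = 2048L)
    for (kind in names(widths)) {
        fp <- moleculeFingerprints(c(two, "C", "CC"), kind)
        expect_identical(ncol(fp), widths[[kind]])
        expect_true(all(fp %in% 0:1))
        ## same molecule, two spellings -> identical rows
        expect_identical(fp[1, ], fp[2, ])
    }
    ## methane vs ethane differ under morgan
    fp <- moleculeFingerprints(c("C", "CC"), "morgan")
    expect_false(identical(fp[1, ], fp[2, ]))
    ## unparseable input violates the precondition
    expect_error(moleculeFingerprints(c("CCO", "bogus("), "morgan"),
                 "valid SMILES")
})

test_that("fingerprint pairs require distinct kinds and honour the beta fallback", {
    fpA <- moleculeFingerprints("CCO", "maccs")
    fpB <- moleculeFingerprints("CCO", "morgan")
    p1 <- fpHashPair(fpA, fpB, M = 1000)
    p2 <- fpHashPair(fpA, fpB, M = 1000)
    expect_identical(p1@hAlpha, p2@hAlpha)  # determinism
    expect_identical(p1@hBeta, p2@hBeta)
    expect_error(fpHashPair(fpA, fpA, M = 1000), "distinct kinds")
    ## an all-zero beta fingerprint falls back to h_beta = 1
    zero <- structure(matrix(0L, 1, 64), kind = "morgan")
    pz <- fpHashPair(fpA, zero, M = 1000)
    expect_identical(ChemBloom:::.u64hex(pz@hBeta), "0000000000000001")
})

test_that("the SMILES pipeline is a pure function end to end", {
    run <- function() {
        cm <- canonicalizeSmiles(c("OCC", "CCN", "c1ccco1"))
        fpA <- moleculeFingerprints(cm$canonicalSmiles, "maccs")
        fpB <- moleculeFingerprints(cm$canonicalSmiles, "path")
        ChemBloom:::.fpHashBatch(fpA, fpB, 4096)
    }
    expect_identical(run(), run())
})

test_that("homolog series fingerprints are more similar than random pairs", {
    series <- homologSeries(baseLength = 7, count = 10, seed = 2)
    rand <- fixtureCorpus(200, seed = 23)
    rand <- setdiff(rand, series)[1:10]
    tanimoto <- function(a, b) {
        num <- sum(a & b)
        if (num == 0) return(0)
        num / sum(a | b)
    }
    pairMean <- function(fp) {
        cmb <- utils::combn(nrow(fp), 2)
        mean(vapply(seq_len(ncol(cmb)), function(j)
            tanimoto(fp[cmb[1, j], ], fp[cmb[2, j], ]), numeric(1)))
    }
    fpS <- moleculeFingerprints(series, "path")
    fpR <- moleculeFingerprints(rand, "path")
    expect_gt(pairMean(fpS), pairMean(fpR))
})

test_that("similar molecules collide in a fingerprint filter more than random strings", {
    series <- homologSeries(baseLength = 8, count = 12, seed = 5)
    rand <- fixtureCorpus(400, seed = 29)[1:12]
    distinctPairs <- function(smiles) {
        h <- ChemBloom:::.fpHashBatch(
            moleculeFingerprints(smiles, "maccs"),
            moleculeFingerprints(smiles, "path"), M = 2^40)
        length(unique(paste(ChemBloom:::.u64hex(h$alpha),
                            ChemBloom:::.u64hex(h$beta))))
    }
    ## homologs share hash pairs (fewer distinct pairs than molecules)
    expect_lte(distinctPairs(series), distinctPairs(rand))
})

test_that("SMILES line files are parsed with comments and ids", {
    path <- tempfile(fileext = ".smi")
    writeLines(c("# header comment", "CCO mol1", "", "c1ccccc1 mol2",
                 "CCN"), path)
    rec <- readSmilesFile(path)
    expect_identical(rec$smiles, c("CCO", "c1ccccc1", "CCN"))
    expect_identical(rec$id, c("mol1", "mol2", NA_character_))
    expect_error(readSmilesFile(tempfile()), "no such file")
})
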