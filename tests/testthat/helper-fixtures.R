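## Shared fixtures, built in code. Corpora are generated once per test run
## and memoised: generation is deterministic, so sharing is safe.

.fixtureEnv <- new.env(parent = emptyenv())

fixtureCorpus <- function(n, seed, mode = "smiles") {
    key <- paste(n, seed, mode, sep = "_")
    if (is.null(.fixtureEnv[[key]]))
        .fixtureEnv[[key]] <- generateCorpus(n, seed = seed, mode = mode)
    .fixtureEnv[[key]]
}

## random ASCII strings without chemistry, for pure hash/filter tests
randomStrings <- function(n, seed, minLen = 5, maxLen = 40) {
    pool <- c(LETTERS, letters, 0:9, "(", ")", "=", "#", "[", "]")
    ChemBloom:::withSeed(seed, {
        lens <- sample(minLen:maxLen, n, replace = TRUE)
        vapply(lens, function(l)
            paste(sample(pool, l, replace = TRUE), collapse = ""),
            character(1))
    })
}

## brute-force membership oracle: stores every added element's index set
## explicitly and re-derives a query's indices on demand
bruteForceOracle <- function(k, M) {
    sets <- list()
    indicesOf <- function(x, scheme = "fnv") {
        p <- stringHashPair(x, scheme, M = M)
        sort(unique(hashIndices(p, k, M)))
    }
    list(
        add = function(x) sets[[length(sets) + 1L]] <<- indicesOf(x),
        contains = function(x) {
            idx <- indicesOf(x)
            all(idx %in% sort(unique(unlist(sets))))
        })
}

writeSmilesFixture <- function(smiles, path = tempfile(fileext = ".smi"),
                               ids = NULL) {
    lines <- if (is.null(ids)) smiles else paste(smiles, ids)
    writeLines(lines, path)
    path
}
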