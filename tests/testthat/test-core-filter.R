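test_that("requiredBits reproduces the sizing formula and its edge cases", {
    ## ceil(-n ln eps / (ln 2)^2), frozen against direct evaluation
    expect_equal(requiredBits(2354965, 0.005), 25969974)
    expect_equal(requiredBits(0, 0.005), 0)
    ## at eps = 0.5 the formula reduces to n / ln 2
    expect_equal(requiredBits(1e6, 0.5), ceiling(1e6 / log(2)))
    expect_identical(requiredBits(1e6, 0.5), 1442696)
    ## domain errors
    expect_error(requiredBits(-1, 0.005), "non-negative")
    expect_error(requiredBits(10, 0), "strictly between")
    expect_error(requiredBits(10, 1), "strictly between")
})

test_that("requiredBits is monotone in n and antitone in epsilon", {
    ns <- c(1, 10, 500, 1e4, 1e6, 1e9)
    for (eps in c(0.5, 0.05, 0.005, 1e-6))
        expect_true(all(diff(requiredBits(ns, eps)) >= 0))
    epss <- c(1e-8, 1e-4, 0.005, 0.05, 0.5, 0.99)
    for (n in c(1, 1000, 1e7))
        expect_true(all(diff(requiredBits(n, epss)) <= 0))
})

test_that("numHashes applies the rounded optimum with the [8, 64] clamp", {
    ## every filter sized at eps = 0.005 uses 8 hashes
    for (n in c(1, 1000, 2354965, 113993087))
        expect_identical(numHashes(requiredBits(n, 0.005), n), 8L)
    ## upper clamp
    expect_identical(numHashes(1000 * 1e4, 1e4), 64L)
    ## interior: (M/n) ln 2 = 10 exactly at M/n = 10/ln 2
    expect_identical(numHashes(round(1000 * 10 / log(2)), 1000), 10L)
    expect_error(numHashes(100, 0), "at least 1")
    ## clamp always holds
    for (ratio in c(0.001, 1, 20, 1e4))
        expect_true(numHashes(ratio * 100, 100) %in% 8:64)
})

test_that("theoreticalFpr matches closed forms and meets the design target", {
    expect_equal(theoreticalFpr(1000, 8, 0), 0)
    expect_equal(theoreticalFpr(5000, 1, 5000), 1 - exp(-1))
    ## an (n, eps) design lands within 10% of its target rate
    for (n in c(1e3, 5e4, 1e6)) {
        M <- requiredBits(n, 0.005)
        k <- numHashes(M, n)
        expect_equal(theoreticalFpr(M, k, n), 0.005, tolerance = 0.1)
    }
    ## monotone in n
    fpr <- theoreticalFpr(1e4, 8, c(100, 500, 1000, 5000))
    expect_true(all(diff(fpr) > 0))
    expect_error(theoreticalFpr(0, 8, 10), "at least 1")
})

test_that("hashIndices performs the double-hashing recurrence", {
    expect_equal(hashIndices(HashPair(3, 5), k = 3, M = 7), c(3, 1, 6))
    expect_equal(hashIndices(HashPair(0, 1), k = 4, M = 4), c(0, 1, 2, 3))
    ## i = 0 always yields h_alpha mod M
    for (a in c(0, 12345, 2^40)) {
        p <- HashPair(a, 977)
        expect_equal(hashIndices(p, 5, 1000)[1], a %% 1000)
    }
    expect_error(hashIndices(HashPair(1, 1), k = 3, M = 0), "at least 1")
    expect_error(hashIndices(HashPair(1, 1), k = 0, M = 7), "at least 1")
})

test_that("all generated indices lie in [0, M) for varied filter sizes", {
    strs <- randomStrings(50, seed = 11)
    for (M in c(1, 2, 7, 64, 1000)) {
        for (s in strs[1:20]) {
            idx <- hashIndices(stringHashPair(s, "fnv", M), k = 16, M = M)
            expect_true(all(idx >= 0 & idx < M))
            expect_true(all(idx == floor(idx)))
        }
    }
})

test_that("added elements are always found (no false negatives)", {
    strs <- unique(randomStrings(10000, seed = 42))
    f <- BloomFilter(n = length(strs), epsilon = 0.005,
                     canonicalize = FALSE)
    f <- bloomAdd(f, strs)
    expect_identical(countAdded(f), as.numeric(length(strs)))
    expect_true(all(bloomContains(f, strs)))
})

test_that("a fresh filter is all zeros and rejects nothing it never saw", {
    f <- BloomFilter(n = 100, canonicalize = FALSE)
    expect_true(all(filterBits(f) == as.raw(0)))
    expect_false(any(bloomContains(f, randomStrings(50, seed = 1))))
})

test_that("adding is idempotent on the bit state and bounded by k", {
    f <- BloomFilter(n = 50, canonicalize = FALSE)
    f1 <- bloomAdd(f, "one-element")
    popcount <- function(x) sum(as.integer(rawToBits(filterBits(x))))
    expect_lte(popcount(f1), numHashFunctions(f1))
    f2 <- bloomAdd(f1, "one-element")
    expect_identical(filterBits(f2), filterBits(f1))
    expect_identical(countAdded(f2), 2)  # calls, not distinct elements
})

test_that("filter warns past design capacity and on empty strings", {
    f <- BloomFilter(n = 3, canonicalize = FALSE)
    f <- bloomAdd(f, c("a", "b", "c"))
    expect_warning(bloomAdd(f, "d"), "capacity")
    expect_warning(
        bloomAdd(BloomFilter(n = 3, canonicalize = FALSE), ""),
        "empty-string")
})

test_that("union is bitwise OR over compatible filters", {
    strs <- unique(randomStrings(100, seed = 5))
    s1 <- strs[1:50]; s2 <- strs[51:100]
    mk <- function() BloomFilter(n = 100, canonicalize = FALSE)
    fBoth <- bloomAdd(mk(), strs)
    fU <- union(bloomAdd(mk(), s1), bloomAdd(mk(), s2))
    expect_identical(filterBits(fU), filterBits(fBoth))
    ## identities
    expect_identical(filterBits(union(mk(), fBoth)), filterBits(fBoth))
    expect_identical(filterBits(union(fBoth, fBoth)), filterBits(fBoth))
    ## incompatibilities
    expect_error(union(mk(), BloomFilter(n = 50, canonicalize = FALSE)),
                 "incompatible")
    expect_error(union(mk(), BloomFilter(n = 100, scheme = "md5",
                                         canonicalize = FALSE)),
                 "incompatible")
})

test_that("contains agrees with a brute-force index-set oracle on small filters", {
    strs <- randomStrings(300, seed = 9)
    for (M in c(16, 64)) {
        f <- BloomFilter(n = 8, M = M, canonicalize = FALSE)
        k <- numHashFunctions(f)
        oracle <- bruteForceOracle(k, M)
        members <- strs[1:8]
        for (x in members) oracle$add(x)
        f <- bloomAdd(f, members)
        verdicts <- bloomContains(f, strs)
        expected <- vapply(strs, oracle$contains, logical(1),
                           USE.NAMES = FALSE)
        expect_identical(verdicts, expected)
    }
})

test_that("FilterSpec enforces its invariants", {
    sp <- FilterSpec(n = 5e4, epsilon = 0.005)
    expect_equal(filterSize(sp), requiredBits(5e4, 0.005))
    expect_identical(numHashFunctions(sp), 8L)
    ## explicit-M spec back-computes its epsilon from theory
    sp2 <- FilterSpec(n = 1000, M = 20000)
    expect_equal(targetFpr(sp2),
                 theoreticalFpr(20000, numHashFunctions(sp2), 1000))
    ## degenerate empty spec is allowed, buildable filter is not
    expect_silent(FilterSpec(n = 0))
    expect_error(BloomFilter(n = 0), "M >= 1")
    expect_error(FilterSpec(n = 10, epsilon = 1.5), "strictly between")
})

test_that("queries on a filter built under one scheme differ from another scheme", {
    strs <- unique(randomStrings(200, seed = 13))
    fF <- bloomAdd(BloomFilter(n = 200, canonicalize = FALSE), strs)
    fM <- bloomAdd(BloomFilter(n = 200, scheme = "md5",
                               canonicalize = FALSE), strs)
    expect_false(identical(filterBits(fF), filterBits(fM)))
})
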