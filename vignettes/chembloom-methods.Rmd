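---
title: "Bloom filters for molecular set membership: models and design"
author: "ChemBloom authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bloom filters for molecular set membership: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ChemBloom)
```

# The problem

Ultra-large chemical libraries -- purchasability catalogues, patent
collections, natural-product databases -- now hold from millions to tens of
billions of molecules. A recurring operation against such libraries is a
pure membership test: *is this exact molecule in the set?* Holding the
SMILES strings themselves takes hundreds of GB at the top end and usually
means querying a remote service, with network latency dominating the cost.

A Bloom filter answers membership queries from a fixed-size bit array with
two one-sided guarantees: an added element is **always** found (no false
negatives), and a never-added element is falsely reported present with a
small, tunable probability. That trade is ideal here: a few GB of memory
suffice for billions of molecules, queries are microseconds, and a false
positive merely sends the user to a definitive (slow) lookup they would
otherwise have made anyway.

# The model

## Sizing

For `n` expected elements and a target false-positive rate $\varepsilon$,
the filter length in bits is

$$M = \left\lceil \frac{-n \ln \varepsilon}{(\ln 2)^2} \right\rceil$$

(`requiredBits()`), and the number of hash probes per element is

$$k = \mathrm{clamp}_{[8,64]}\!\left(\mathrm{round}\!\left(\tfrac{M}{n}\ln 2\right)\right)$$

(`numHashes()`). The unclamped value is the textbook optimum for an
`M`-bit filter holding `n` elements; the clamp bounds work per query on
both sides. At $\varepsilon = 0.005$ the optimum is $\approx 7.64$, so
every filter sized at that rate uses exactly 8 hash functions. The clamp's
floor can push `k` above the optimum for very permissive designs
($\varepsilon \gtrsim 0.01$), costing a little theoretical headroom; we
keep the clamp because bounded probe counts are worth more than the last
few percent of FPR at rates nobody deploys.

After `n` insertions the expected false-positive rate is the standard
approximation $(1 - e^{-kn/M})^k$ (`theoreticalFpr()`), which the
evaluation harness uses as its reference curve.

`M` is rounded up to a whole bit only -- no rounding to bytes or powers of
two, and no primality adjustment. Sizing reports print GB under both the
$2^{30}$-bytes and $10^9$-bytes conventions, labelled, because published
per-library figures follow the former.

## Double hashing

Each element contributes two 64-bit hashes $(h_\alpha, h_\beta)$ and is
probed at

$$h_i = (h_\alpha + i\, h_\beta) \bmod M, \qquad i = 0, \dots, k-1,$$

with the sum taken modulo $2^{64}$ before reduction (deterministic,
platform-independent unsigned arithmetic). Two restrictions keep the probe
stride sound: $h_\beta \ne 0$, and $h_\beta \bmod M \ne 0$; when violated,
$h_\beta$ is replaced by 1, which strides through every residue class for
any `M`.

## String hashing

The `"fnv"` scheme hashes the UTF-8 bytes of the (canonical) SMILES.
$h_\alpha$ is plain FNV-1a 64-bit under the standard offset basis.
$h_\beta$ required more care than one might expect, and the construction is
a deliberate design decision of this package:

* Two forward FNV-1a runs that differ only in their offset basis are
  **strongly correlated**: the per-byte update `(h XOR byte) * prime`
  propagates a basis difference almost additively (`d -> d * prime`), so
  for equal-length inputs the difference of the two hashes is nearly
  constant.
* Worse, FNV-1a's trailing multiplication by an odd prime leaves bit 0 of
  the output *exactly* the XOR of the input bytes' low bits (and the next
  few bits approximately so), identically for any basis and any byte
  order. Hence bit 0 of $h_\alpha \oplus h_\beta$ is constant; since `M`
  from the sizing rule is typically even, half of every element's probes
  fall into a single parity class of the array. Measured on a
  $2 \times 10^4$-element fifty-fifty experiment, this quadruples the
  false-positive rate over theory (about 1.9% against a 0.5% design).

$h_\beta$ is therefore FNV-1a under a second documented basis
(`fnvOffsetBases()["beta"]`, itself the FNV-1a hash of the byte `0xff`),
consuming the bytes back-to-front, finished with the bijective splitmix64
avalanche mix. The finalizer destroys the shared linear structure; after
it, the empirical FPR matches theory and the $(h_\alpha \bmod M,
h_\beta \bmod M)$ joint distribution is indistinguishable from
independence by a chi-square test. The exported `fnv1a64()` remains plain
FNV-1a and reproduces the published reference vectors exactly.

The `"md5"` scheme splits the 128-bit digest into big-endian halves --
first half $h_\alpha$, second $h_\beta$ -- and needs no correction: the
halves of a cryptographic digest are independent by construction. `"md4"`
is an alias of `"md5"`: the two digests' behaviour in this role is
indistinguishable, and MD5 is the one with a universally available
reference. Both schemes hit the theoretical FPR curve; FNV is the default
because it is simpler and faster.

## Fingerprint hashing

For comparison with structure-based practice, a filter can hash pairs of
binary fingerprints instead of strings: any two distinct kinds out of
`"maccs"` (166 structural keys), `"morgan"` (circular/ECFP4, 4096 bits),
`"atompair"` (atom-pair descriptors folded to 2048 bits), `"path"`
(linear-fragment fingerprint, 1024 bits) -- six unordered pairs. Each
fingerprint's bit vector is read as a big-endian integer reduced modulo
$2^{64}$ (i.e. its trailing 64 bits) to give $h_\alpha$ and $h_\beta$.

This conversion is deliberately *not* re-hashed through FNV. Fingerprints
are designed so that similar molecules have similar bit vectors -- the
exact opposite of the avalanche property a filter hash needs -- and the
point of the comparison is to measure the consequence. Re-hashing the
fingerprint bytes would erase the phenomenon under study. The observed
consequences on synthetic corpora: fingerprint-pair schemes sit above the
string scheme at every useful filter size, often by an order of magnitude,
their curves plateau instead of falling to zero (many distinct molecules
share identical trailing-64-bit patterns, a size-independent collision
floor), and they show noisy non-monotonic stretches tied to divisibility
interactions between clustered $h_\beta$ values and particular `M` values.

Widths follow the fingerprinting backend: MACCS's 166 keys arrive in a
168-bit frame, ECFP4 in 4096 bits, the path fingerprint in a 1024-bit
frame. Only the atom-pair kind has a configurable fold width (`nbits`,
default 2048, applied as `descriptor-code mod nbits`); a fixed
reference-descriptor basis was rejected because small synthetic molecules
fall outside common drug-derived descriptor sets and would fingerprint to
all-zero vectors.

## Canonicalization

SMILES admit many spellings per molecule, so filters hash the *canonical*
isomeric SMILES by default (`canonicalizeSmiles()`, backed by OpenBabel);
a filter records whether it canonicalizes and applies the same rule at
query time. Canonicalization is idempotent, and unparseable inputs are
flagged rather than fatal: skipped (and counted) during builds, reported
absent at query time -- an unparseable string cannot have been added as a
molecule. A `stripStereo` switch removes stereo marks and isotope labels
before canonicalization for corpora where stereoisomers should collapse to
one record; it is a text-level strip, documented as such.

# The experiments

`fiftyFiftyFpr()` implements the measurement protocol: deduplicate,
shuffle once under a given seed, add the first half, query the disjoint
second half; every positive among the second half is a false positive.
Deduplication precedes the split because a true member leaking into the
query half would be scored as a false positive that is not one.
`sizeSweep()` repeats the measurement across strictly increasing filter
sizes with a single shared split, so curves at different sizes and schemes
are directly comparable; sizes default to powers of two around the sizing
rule's `M` for the corpus at hand, spanning saturation (`M` far below
design) to vanishing FPR (`M` far above).

One regime deserves a note: deep in saturation (filters several times
*smaller* than design), fingerprint schemes can measure *below* the string
scheme. The degeneracy that ruins them elsewhere -- many molecules sharing
one hash pair -- also means fewer distinct bit patterns are written, so
the array fills more slowly. Every filter in that regime is useless (FPR
near 1); comparisons are made at and above the design size, where the
string scheme's advantage is uniform.

`queryBenchmark()` reports seeded, repeatable latency summaries for raw
hash lookups and canonicalize-plus-lookup separately. Latencies are
hardware-bound, so the benchmark only reports; nothing in the test suite
asserts a timing.

# Synthetic corpora

`generateCorpus()` makes experiments self-contained: no chemical database
download. In `smiles` mode it grows random molecular trees over
{C, N, O, S, F, Cl, Br} with explicit valence bookkeeping (element draw
weighted toward carbon 10:3:3:1 to keep compositions organic-like),
occasional double bonds (p = 0.15) and one optional ring closure (p = 0.25
for molecules of 5+ atoms), up to 12 heavy atoms by default; every
construction is parseable by design, and the batch is canonicalized and
deduplicated *in canonical space* -- the same space the filter hashes --
until `n` unique records exist. Generation is a pure function of
`(n, seed, mode, maxHeavyAtoms, palette)`.

What the generator emulates: corpus-scale sets of unique, valid, canonical
SMILES with realistic string lengths and enough structural variety that
string hashes behave as on real libraries (string hashing is
content-agnostic, so FPR results transfer directly). What it does not
emulate: drug-like property distributions, aromatic ring systems,
realistic functional-group frequencies, or any particular database's
structural statistics. Fingerprint-scheme results are therefore
qualitative -- the clustering and collision-floor phenomena are real and
reproduced, but their magnitudes on (say) a natural-product library would
differ. Passing tests show the machinery and the comparative ordering, not
database-specific curves.

`homologSeries()` emits single-substitution variants of one linear
scaffold -- a worst case for fingerprint hashing, used to demonstrate
collision clustering among similar molecules.

# Numerical and format choices

* All hash arithmetic is unsigned 64-bit with wraparound, in compiled
  code; 64-bit values cross the R boundary as 8-byte big-endian raw
  vectors because doubles cannot represent all of them exactly.
* The on-disk format (version 1) is fixed little-endian with LSB-first bit
  packing; bit `i` of the filter is bit `i mod 8` of payload byte
  `floor(i/8)`. Readers reject unknown magic or versions and verify that
  the payload length equals `ceiling(M/8)` bytes. The header records the
  scheme label and the canonicalization flag, so a filter cannot be
  queried under a scheme other than the one it was built with.
* Duplicate adds are not detected (`countAdded` counts calls): distinct
  counting would need memory proportional to the set, defeating the
  structure's purpose. Capacity over-runs warn and continue -- the filter
  still has no false negatives; only its realized FPR degrades.
* Empty strings are hashable (FNV of zero bytes is the offset basis) but
  flagged with a warning, since they usually signal an upstream parsing
  bug.
* Degenerate inputs: `n = 0` yields a valid empty *spec* but no buildable
  filter (`M >= 1` is required to allocate); `M = 0` anywhere in the hash
  path is a domain error.

# Problem sizes used by the test suite

The packaged experiments run at desk scale, chosen to finish in minutes on
one CPU while leaving binomial noise well below the effects measured: the
headline FPR experiment uses $10^5$ unique synthetic canonical SMILES
(5 x 10^4 built, 5 x 10^4 queried; 4-sigma binomial tolerance around
theory), the string-vs-fingerprint comparison uses $2 \times 10^4$
molecules across 8 matched sizes, and the property suites use $10^4$ to
$10^5$ random strings. A worked example:

```{r sizing}
sizingTable(c(ChemBL = 2354965, PubChem = 113993087), epsilon = 0.005)
```

```{r fpr}
corpus <- generateCorpus(2e4, seed = 7)
M <- requiredBits(1e4, 0.005)
fiftyFiftyFpr(corpus, M, scheme = "fnv", seed = 7)
theoreticalFpr(M, numHashes(M, 1e4), 1e4)
```

# Known limitations

* No deletion, counting variants, or partitioned/scalable filters; a
  filter's capacity is fixed at build time (though `union()` merges
  filters of identical design, supporting incremental corpus builds).
* Canonical-SMILES equality is toolkit-relative: a filter built with one
  canonicalizer version should be queried through the same one. The filter
  file records that canonicalization was applied, but not the backend
  version.
* The MD4 scheme name is an alias for MD5 rather than a separate legacy
  digest implementation.
* InChI and SELFIES representations are out of scope; nothing in the
  design prevents them, but no reference behaviour is packaged.
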