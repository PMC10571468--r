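# ChemBloom

Space-efficient membership testing for large chemical libraries.

Screening pipelines constantly ask whether a proposed structure is already
in some reference set — purchasable in a vendor catalogue, claimed in a
patent collection, known as a natural product. The sets are huge (millions
to billions of molecules) and the question is exact-membership, so a Bloom
filter is the right tool: a fixed-size bit array that **never misses an
added element** and reports a never-added element present only with a
small, tunable probability ε. A filter for two billion molecules at
ε = 0.005 fits in under 3 GB of RAM; queries take microseconds.

ChemBloom implements Bloom filters specialised for molecules:

- **Sizing.** `M = ceil(-n ln ε / (ln 2)²)` bits for `n` elements at target
  rate ε (`requiredBits()`), with `k = round((M/n) ln 2)` hash probes
  clamped to [8, 64] (`numHashes()`); every filter sized at ε = 0.005 uses
  exactly 8 hashes.
- **Double hashing.** Probes at `h_i = (h_α + i·h_β) mod M`, with `h_β ≠ 0`
  and `h_β mod M ≠ 0` enforced. Two base-hash families: canonical-SMILES
  string hashing (FNV-1a 64-bit, the default, or an MD5 digest split) and —
  for comparison — pairs of structure fingerprints (MACCS, Morgan/ECFP4,
  atom-pair, path) read directly as integers. On equal filters, string
  hashing tracks the theoretical false-positive curve while every
  fingerprint pair sits far above it: fingerprints are similarity-
  preserving by design, the opposite of the avalanche behaviour a filter
  hash needs.
- **Canonicalization.** Filters hash canonical SMILES (OpenBabel-backed),
  so any spelling of a molecule queries correctly; the canonicalization
  flag travels with the filter.
- **A portable on-disk format** (fixed endianness and bit order, versioned
  header recording the scheme), so filters build once and ship anywhere.
- **An evaluation harness** (fifty-fifty split protocol, size sweeps,
  sizing tables, query micro-benchmark) and a **deterministic synthetic
  SMILES generator**, so every experiment runs without downloading a
  chemical database.

## Worked example

```r
library(ChemBloom)

sizingTable(c(ChemBL = 2354965, PubChem = 113993087))
#>            name         n       bits     bytes   gb_2pow30      gb_1e9 k
#> ChemBL   ChemBL   2354965   25969974   3246247 0.003023303 0.003246247 8
#> PubChem PubChem 113993087 1257087655 157135957 0.146344264 0.157135957 8

corpus <- generateCorpus(20000, seed = 7)          # unique canonical SMILES
f <- BloomFilter(n = 10000, epsilon = 0.005, canonicalize = FALSE)
f <- bloomAdd(f, corpus[1:10000])
f
#> BloomFilter
#>   scheme: fnv
#>   M = 110278 bits, k = 8, design n = 10000 (epsilon = 0.005)
#>   added: 10000; occupancy: 51.781%

mean(bloomContains(f, corpus[1:10000]))            # members: always found
#> [1] 1
mean(bloomContains(f, corpus[10001:20000]))        # disjoint half: FPR
#> [1] 0.0058
theoreticalFpr(filterSize(f), 8, 10000)
#> [1] 0.005017005
```

The sizing table says a 2.35-million-compound library needs 0.003 GB and a
114-million-compound one 0.146 GB (2³⁰-bytes convention) at ε = 0.005, both
with 8 hash functions. The filter example shows the two Bloom guarantees:
all 10,000 added molecules are found, and the measured false-positive rate
on 10,000 never-added molecules (0.58%) matches the 0.50% theoretical rate
within binomial noise.

A shell interface wraps the same functions:

```sh
Rscript inst/scripts/chembloom gen   --n 10000 --seed 7 --out corpus.smi
Rscript inst/scripts/chembloom build --in corpus.smi --out corpus.bloom --epsilon 0.005
Rscript inst/scripts/chembloom query --filter corpus.bloom "CCO" "c1ccccc1O"
Rscript inst/scripts/chembloom size  --n 2354965,113993087 --epsilon 0.005
```

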