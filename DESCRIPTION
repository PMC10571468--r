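Package: ChemBloom
Title: Bloom Filters for Molecular Set Membership
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
        role = c("aut", "cre"))
Description: Space-efficient probabilistic membership testing for ultra-large
        chemical libraries. Implements Bloom filters specialised for molecules,
        hashing either canonical SMILES strings (FNV-1a or MD5 double hashing)
        or pairs of structure fingerprints (MACCS, Morgan/ECFP, atom-pair,
        path), with principled sizing from a target false-positive rate, a
        portable on-disk filter format, a deterministic synthetic-SMILES
        corpus generator, and an evaluation harness measuring empirical
        false-positive rates against theory.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports: methods, stats, utils, Rcpp, BiocGenerics, S4Vectors, ChemmineR,
        ChemmineOB
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
biocViews: Cheminformatics, DataRepresentation, Infrastructure
RoxygenNote: 7.3.3
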