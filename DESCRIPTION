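Package: habid
Title: Gel-Fingerprint and 18S rDNA Typing of Harmful Algal Bloom Isolates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-track species discrimination for harmful-algal-bloom (HAB)
    isolates. Track one scores protein and isozyme gel fingerprints into a
    binary band-by-lane matrix, computes per-lane monomorphic, polymorphic
    and unique band counts and polymorphism percentages, and clusters lanes
    by Dice, Jaccard or simple-matching similarity with UPGMA dendrograms.
    Track two identifies 18S rDNA queries against a local reference library
    by exact global affine-gap alignment and percent-identity ranking, and
    builds neighbor-joining, UPGMA and Fitch-parsimony phylogenies with
    seeded bootstrap supports and strict majority-rule consensus trees.
    A synthetic-data module generates gel lanes and tree-evolved sequences
    with known ground truth, including a deterministic four-isolate study
    fixture, so the whole pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    S4Vectors,
    methods,
    stats,
    utils,
    ape,
    phangorn,
    Biostrings,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
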