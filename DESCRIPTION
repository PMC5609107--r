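Package: genospecies
Title: Bacterial Genospecies Delineation from ANI, wgMLST and Pangenome Openness
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for delineating bacterial genospecies from whole-genome data:
    Gegenees-style fragmented genome similarity, fragment-based average nucleotide
    identity (ANI) with single-linkage threshold clustering, whole-genome MLST allele
    profiling with UPGMA dendrograms, ortholog-family pangenomics via Markov
    clustering of a protein similarity graph, permutation-based pangenome openness
    (Heap's law alpha) and exponential-decay core-genome extrapolation, Kimura
    2-parameter marker distances with neighbor joining, and a combined ANI + alpha
    species-support decision. Includes a deterministic synthetic genome-cohort
    generator with known cluster structure for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    ape,
    Matrix,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
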