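Package: motifhash
Title: Label-Hash Substructure Matching of Protein Structural Motifs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-phase matching of small structural motifs (C-alpha
    coordinates with allowed residue labels) against collections of protein
    structures.  Targets are preprocessed into a persistent table of
    geometrically constrained residue triples indexed by sorted residue-label
    keys, so partial matches of any motif can be looked up in constant time.
    Partial matches are expanded to complete matches by depth-first match
    augmentation under an RMSD rejection threshold, using optimal rigid-body
    superposition computed from the largest root of the quaternion
    characteristic polynomial.  Each match receives a corrected nonparametric
    p-value from a kernel-density motif profile with a point weight at
    infinity that accounts for targets that could have matched but did not.
    Includes a generator for protein-like synthetic targets with planted,
    noise-perturbed motif instances for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    parallel,
    jsonlite,
    xml2,
    bio3d
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
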