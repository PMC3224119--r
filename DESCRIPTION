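Package: poolscore
Title: Simulation and Reference-Based Scoring of Pooled-BAC and WGS Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing sequencing regimes for complex genomes in
    silico. Builds minimum-tiling-path (MTP) BAC layouts and clone pools over
    a reference, simulates Roche/454-style linear and paired reads with
    non-uniform coverage and a homopolymer-aware error model, and simulates
    Sanger BAC-end sequences (BES). Assemblies are evaluated against a known
    reference with five assembler-independent correctness scores (match,
    relocation, inversion, redundancy, coverage) computed from per-position
    closest-match tables, and scaffolds can be ordered and oriented into
    gapped pseudomolecules using BES hits. Includes a synthetic-reference
    generator with controlled GC, homopolymer and repeat content, a BLAST
    tabular (outfmt 6) parser and an exact anchor matcher for test-scale
    alignment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
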