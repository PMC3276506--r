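Package: phagerec
Title: Breakpoint Mapping and Strand-Annealing Recombination Models for
    Bacteriophage Hybrid Genomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for characterising recombinant (hybrid) bacteriophage
    genomes from sequence alone: in-silico restriction digestion of linear
    genomes and localisation of band differences between two digests;
    per-position parentage painting of a hybrid against its two parents via
    anchored three-way alignment, with crossover-interval and
    microhomology-window inference; detection of pseudo-palindromes and the
    cruciform four-way junctions they extrude, with assignment of
    junction-resolving endonuclease (Endo I) cleavage bonds; and sequence-level
    simulators of two single-strand-annealing recombination mechanisms,
    cleavage at equivalent sites (CESA) and cleavage at nonequivalent sites
    with 5' resection (CNSA).  A synthetic-genome generator produces parent
    pairs and spliced hybrids with known truth so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    seqinr
Config/testthat/edition: 3
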