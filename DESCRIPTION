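Package: satcomp
Title: Comparative Satellitome Analysis from Low-Coverage Sequencing Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for discovering and comparing satellite DNA (satDNA)
    families across related genomes from low-coverage unassembled short
    reads. Implements similarity-graph read clustering, tandem-repeat
    period estimation and monomer consensus building, cross-species
    abundance and presence matrices, Dollo-parsimony inference of
    hybridization/polyploidization history on a species chain,
    RPKM-based satDNA transcription profiling with
    transcription-to-genome activity ratios, fuzzy IUPAC motif scanning
    (CENP-B box-like motifs) and per-column conservation profiles, plus
    a seeded synthetic-data generator that emulates nested satDNA
    libraries for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
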