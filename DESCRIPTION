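Package: biopepscan
Title: Exhaustive Bioactive-Peptide Mining in Proteomes with In-Silico Digestion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Locates every exact occurrence of a curated bioactive-peptide
    library (e.g. a BIOPEP-UWM export) within a proteome using a multi-pattern
    Aho-Corasick automaton, aggregates hits by biological-activity category,
    cross-references carrier proteins with differential gene expression, and
    classifies whether gastrointestinal proteases (trypsin, chymotrypsin,
    pepsin, elastase) could release each matched peptide intact. Ships a
    seeded synthetic-data generator (proteomes with planted peptides, peptide
    libraries with computed masses, expression tables) so the whole pipeline
    is testable without external downloads, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    BiocGenerics,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
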