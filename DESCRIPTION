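Package: crisprnet
Title: CRISPR Spacer-Based Inference of Bacteria-Mobile Genetic Element
    Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects CRISPR arrays in bacterial genomes and metagenome
    assemblies (de novo from the repeat-spacer structure, or guided by a
    library of known repeats), extracts and deduplicates spacers, matches
    them against a phage/plasmid (mobile genetic element) database with a
    seeded nucleotide search and Karlin-Altschul e-value statistics, applies
    identity/coverage/e-value retention filters, summarises matches with a
    greedy covering-set selection of MGEs and hosts, and emits spacer-MGE
    and host-MGE bipartite interaction networks with connected-component
    and module composition reports. Includes a seeded synthetic-data
    generator that plants mutated MGE segments as CRISPR spacers so the
    whole pipeline is testable end to end without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
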