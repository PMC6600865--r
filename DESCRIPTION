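Package: tfkit
Title: Data Structures and Queries for Transcription Factor Bioinformatics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrative work with human transcription factors (TFs):
    harmonized TF catalogs from CISBP-, HOCOMOCO- and Gene Ontology-style
    snapshots keyed by HGNC gene symbols, with set-overlap and class-frequency
    summaries; GMT gene-set collections of TF targets with parsing of
    MSigDb-style motif_gene_version set names; interval queries over
    tabix-indexed genome-wide binding-affinity score tracks and ENCODE-style
    narrowPeak ChIP-seq files; joins between TF catalogs or TF target sets and
    GWAS-catalog records; and a deterministic synthetic-fixture generator so
    every workflow runs offline. A command-line interface exposes the main
    workflows as subcommands.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    Rsamtools,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea
Config/testthat/edition: 3
RoxygenNote: 7.3.3
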