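Package: aptrace
Title: Analysis of Multi-Round HTS-SELEX Aptamer Selections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing high-throughput sequencing data from
    multi-round SELEX aptamer selections. Reads multiplexed FASTQ/FASTA pools,
    demultiplexes by barcode, extracts the random region between constant
    flanks, builds per-pool prevalence censuses, clusters related sequences
    around abundant founders with an edit-distance rule and a k-mer profile
    prefilter, ranks candidates by round-over-round enrichment rate, screens
    specificity against reference (counter-selection) pools including
    pH-adjusted controls and species orthologs, and profiles the within-cluster
    mutational landscape to nominate affinity-improving variants. A generative
    SELEX simulator (Langmuir binding, GC-biased open versus emulsion PCR,
    PCR mutagenesis, multinomial sequencing) provides ground-truthed synthetic
    campaigns for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
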