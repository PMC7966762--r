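Package: magconcord
Title: Validation Toolkit for Long-Read Metagenome-Assembled Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing genomes assembled from long-read metagenome
    sequencing against an independent short-read assembly of the same
    community. Computes the concordance statistic (kappa) that links
    short-read contig bins to long-read chromosome-scale contigs from BLAST
    tabular alignments; classifies genome quality from completeness and
    contamination estimates and summarises quality tables across sequence
    correction procedures; screens per-base coverage profiles for anomalous
    intervals indicative of mis-assembly; evaluates sequence correction via
    predicted-gene length ratios against best-hit orthologues; and triages
    circular sub-megabase replicons into small genomes, chromids,
    viruses/phages, plasmids and artefactual fragments using annotation
    evidence. A seeded synthetic-data generator produces complete test
    scenarios (genomes, fragmented binned contigs, alignment tables, coverage
    profiles, gene tables and replicon panels) with recorded ground truth, so
    the whole pipeline can be exercised without sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    withr,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
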