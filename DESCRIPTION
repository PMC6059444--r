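Package: contamcheck
Title: Consensus Estimation of Foreign-DNA Contamination in Prokaryotic
    Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the foreign-DNA contamination level of prokaryotic
    genome assemblies by combining six independent detectors in a consensus
    ranking: best-hit classification of SSU rRNA (16S) genes, top-3
    lowest-common-ancestor (LCA) classification of ribosomal proteins, a
    single-copy marker redundancy estimator of completeness and
    contamination, a signature-kmer pseudo-read classifier with a confidence
    threshold, a MEGAN-like bit-score-collapsing protein LCA classifier with
    self-match exclusion, and reference-free tetranucleotide-frequency
    binning with a largest-group statistic. Includes NA-aware rank
    aggregation of the six methods, Spearman congruence analysis,
    per-segment genome maps with GC and sequencing-coverage tracks,
    decontaminated FASTA output, and a synthetic-data generator producing
    taxonomies, reference genomes and proteomes, marker panels, chimeric
    query assemblies, reads and exact ground truth, so the whole pipeline is
    testable without any external database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    mclust,
    stats,
    utils
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
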