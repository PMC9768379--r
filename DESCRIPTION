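Package: poliseq
Title: RNA Polymerase I NET-Seq Occupancy, Pause-Site and Polymerase Gap
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Single-nucleotide analysis of RNA polymerase I transcription
    elongation on the ribosomal DNA. Provides an annotated rDNA template
    model, a synthetic NET-Seq read simulator with sequence-dependent
    pausing and mature-rRNA contamination, UMI deduplication, adaptor
    trimming and exact single-locus 3'-end mapping into per-position
    occupancy profiles, replicate- and strain-level occupancy statistics
    (position-wise Welch tests, Kolmogorov-Smirnov region comparisons,
    Spearman correlations, principal component analysis), top-percentile
    pause-site calling with differential sequence logos scored by
    Jensen-Shannon divergence and permutation tests, and quantification
    of large polymerase-free gaps in Miller chromatin spread position
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
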