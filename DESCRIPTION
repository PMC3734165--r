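Package: rootnet
Title: Small RNA-Mediated Gene Regulatory Networks from Tissue-Enriched
    Small RNA, Degradome and Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds small RNA (sRNA) mediated gene regulatory networks for
    plant root tissues. Normalizes multi-library sRNA read counts to reads
    per million, extracts compartment-enriched (root tip versus whole root)
    and Argonaute 1 (AGO1) immunoprecipitation-enriched sRNA species,
    profiles their 5' terminal nucleotide and length distributions, predicts
    target binding sites on a transcriptome by antiparallel complementarity
    with a position-weighted penalty score, validates predicted sites
    against degradome (PARE) libraries using the 8th-12th nucleotide
    cleavage window, a two-distinct-signature rule and automated target-plot
    (t-plot) categories, checks validated targets for contrary expression
    across root zones, and assembles the surviving interactions into a
    bipartite regulatory network. Ships a synthetic-data generator with
    planted ground truth so the full pipeline can be exercised and its
    recovery measured without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
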