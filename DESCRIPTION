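Package: seedclust
Title: Quality-Aware Minimizer Clustering of Long Transcriptomic Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: De novo clustering of long-read (PacBio/ONT) transcriptome
    datasets into gene families. Reads are sketched with (canonical)
    minimizers; seeds whose base-call quality implies a high probability of
    being error-free ("high-confidence seeds") represent clusters, and the
    representation is updated dynamically as reads join. An optional
    iterative merging pass joins clusters that share a large fraction of
    their high-confidence seeds. Includes external clustering-evaluation
    metrics (homogeneity, completeness, V-measure, Rand and adjusted Rand
    index) and a synthetic long-read transcriptome generator with ground
    truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
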