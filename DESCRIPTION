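Package: oriclass
Title: Classification of Budding-Yeast Replication Origins by ORC Binding
    Mechanism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for classifying Saccharomyces cerevisiae DNA replication
    origins by the mechanism through which the origin recognition complex
    (ORC) binds them.  In-vivo ORC-origin affinity is estimated from
    ChIP-chip peak-area ratios under ORC depletion, and in-vitro ORC-DNA
    affinity from electrophoretic mobility shift assay (EMSA) titrations
    fitted to a one-site binding hyperbola and from genomic-EMSA array
    signals.  The package provides sliding-window peak calling with a
    Gaussian background model, apparent-Kd fitting and threshold
    classification against a reference origin, k-means clustering of
    genomic-EMSA signal profiles, position-weight-matrix motif scanning
    against a k-th order Markov genome background, nucleosome-depleted
    region measurement around ORC binding sites, replication-timing
    association statistics, and a fully synthetic study generator with
    known per-origin ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
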