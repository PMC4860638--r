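Package: focalWave
Title: Wavelet-Based Detection of Recurrent Focal Copy-Number Alterations
    from Whole-Genome Sequencing Read Depth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects recurrent focal DNA copy-number alterations across
    cohorts of tumor/normal whole-genome sequencing pairs. Per-sample
    read-depth log2-ratio tracks are decomposed with a stationary Haar
    wavelet transform; level-wise hard thresholding retains only
    high-frequency structure, so narrow (focal) alterations are separated
    from broad arm-level events. Sign-filtered high-frequency signals are
    summed across patients, partitioned into candidate clusters by gap
    distances, and assessed with permutation-based false discovery control.
    Includes reference-gap and low-mappability masking, a negative-binomial
    cohort simulator with planted alterations, and evaluation utilities.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Rsamtools,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
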