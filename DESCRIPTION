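Package: nitrobin
Title: Differential-Coverage Genome Binning and Nitrification Kinetics on
    Synthetic Nitrifier Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying two-guild nitrifying enrichment cultures in
    silico. Generates labelled synthetic metagenome inputs (genome-specific
    Markov-chain contigs, multi-timepoint coverage trajectories, paired-end
    link graphs, planted single-copy markers), bins contigs into draft
    genomes by multidimensional scaling of differential coverage followed by
    k-medoids clustering, composition-based refinement and paired-end
    recruitment, and scores bins against planted truth (adjusted Rand index,
    marker completeness and contamination). Also estimates nitrification
    growth kinetics from bottle-experiment chemistry: exponential-window
    log-linear growth rates with an R-squared acceptance rule, lag durations,
    Monod (mu_max, Ks) fits, qPCR standard-curve quantification, and a
    Monod-limited ammonia-to-nitrite-to-nitrate cascade simulator for the
    coupled ammonia-oxidizer/nitrite-oxidizer system.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    cluster,
    deSolve,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
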