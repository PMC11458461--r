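Package: timenorm
Title: Two-Stage Normalization for Time-Course Microbiome Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Normalization of longitudinal microbiome count tables in two
    stages: intra-time normalization scales samples within each
    condition-by-timepoint group using common dominant features, and bridge
    normalization chains scale factors across conditions and adjacent time
    points through a set of stable features selected with a zero-inflated
    log-normal ratio model, Bhattacharyya-distance clustering and
    likelihood-ratio screening.  Includes reference implementations of
    total-count, TMM, CSS and GMPR scaling for benchmarking, a zero-inflated
    negative binomial Gaussian-copula simulator for time-course counts with
    ground truth, and evaluation utilities (relative root mean square error,
    a permutation spline test for differential abundance, and a benchmark
    driver).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    edgeR,
    splines,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
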