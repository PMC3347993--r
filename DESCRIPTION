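Package: RNAfoldBench
Title: Energy-Based RNA Secondary Structure Prediction and Benchmark Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking energy-based RNA secondary structure
    prediction. Implements minimum free energy folding, McCaskill-style
    partition function and base-pair probabilities, maximum expected accuracy
    (MEA), gamma-centroid and pseudo-MEA estimators over a reduced, pluggable
    nearest-neighbor energy model; sensitivity/PPV/F-measure accuracy metrics
    with unweighted, weighted and similarity-weighted class averages; bootstrap
    percentile confidence intervals with an Anderson-Darling normality
    diagnostic and one- and two-sided permutation tests; and a seeded synthetic
    benchmark generator that emulates class-structured reference datasets so
    the full analysis pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    boot,
    nortest,
    Biostrings,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
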