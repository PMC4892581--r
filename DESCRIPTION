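Package: boclust
Title: Bootstrap-Stability Detection of Variable Modules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects modules (communities) in sets of correlated variables
    by combining a base clustering algorithm with a measure of partition
    stability under bootstrap resampling. Every candidate cluster count is
    scored by the summed across-resample variance of the pairwise
    co-clustering indicators, normalized against a column-permutation null
    that preserves marginals while destroying correlations; the count with
    the lowest normalized criterion is selected and tested against the
    null's lower 2.5 percentile. Local minima of the criterion profile hint
    at hierarchical (nested) module structure. Includes generators for flat
    and hierarchical additive-module synthetic data (normal, beta or
    uniform components), tidy and plot methods for fitted profiles, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    cluster,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
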