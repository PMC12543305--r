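Package: edrnet
Title: Exponential Distance Rule Network Models for Region-Level Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing region-level structural brain networks
    ("projectomes") against the exponential distance rule (EDR): skeleton-based
    measurement of neuronal main-cable and Euclidean cable lengths with
    exponential decay-rate fitting, construction of column-normalized
    region-to-region weight matrices from synapse tables, a one-parameter
    maximum-entropy EDR random-network generator over a region distance matrix
    (with the constant distance rule as its lambda = 0 limit), a suite of
    binary and weighted network properties with RMSD model-versus-data
    comparison across a lambda grid, link-weight asymmetry and hierarchy
    analysis, hierarchical clustering of information-flow profiles, and a
    synthetic-data generator emulating the statistical structure of the
    Drosophila projectome for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
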