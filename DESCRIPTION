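Package: kinmotif
Title: Kinetic Motif Discovery for Synthetic Gene Circuit Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exhaustively simulates a synthetic transcriptional repression
    cascade over a binned grid of kinetic parameters under deterministic and
    noise-perturbed dynamics, scores every parameter set against a target
    steady-state profile, clusters the functional sets into recurring
    combinations of efficiency levels ("kinetic motifs"), ranks them into a
    performance handbook, and answers design-repair and design-improvement
    queries against that handbook in terms of ribosome binding site (RBS) and
    protein degradation tag (PDT) substitutions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
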