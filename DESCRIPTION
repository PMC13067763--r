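Package: bepitools
Title: Base-Editing Performance Scoring and Directed-Evolution Screen Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis toolkit for cytosine base-editor engineering campaigns:
    the Base Editor Performance Index (BEPI) formula family with its
    scenario-grid evaluation and selection criteria, amplicon-sequencing
    quantification of C-to-T editing and indel outcomes in PAM-relative
    protospacer coordinates, balanced degenerate-codon site-saturation library
    design by exact cover, multi-round directed-evolution enrichment analysis
    with paired-read overlap merging, protein pocket-geometry aggregation and
    trilateration, and seeded simulators for edited amplicon reads and
    iterative selection rounds.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    methods,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
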