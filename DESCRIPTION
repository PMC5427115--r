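Package: fluxscape
Title: Constraint-Based Flux Analysis of Antibiotic-Producing Metabolic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidy tools for constraint-based analysis of genome-scale
    metabolic models of secondary-metabolite producers. Reads models from
    SBML (Level 3 'fbc') or a hand-writable tabular format, solves flux
    balance analysis (FBA), parsimonious FBA and flux variability problems
    with a built-in bounded-variable simplex solver, traces Pareto fronts
    between growth and product synthesis, scans for overexpression targets
    by enforced-objective flux scanning (FSEOF), and integrates
    quartile-thresholded transcriptomics through the iMAT mixed-integer
    consistency maximization. Ships a synthetic-data module that generates
    toy networks and expression tables with analytic ground truth so every
    stage of the pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
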