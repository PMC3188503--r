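Package: forevol
Title: Individual-Based Simulation of Evolving Foraging Decision Making
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Event-driven, spatially explicit individual-based model of
    foraging in lattice resource worlds with uniform or patchy item
    distributions. Foragers alternate mutually exclusive behavioral actions
    (MOVE, FOODSCAN, MOVETOFOOD, EAT) under one of two evolvable
    decision-making architectures: a restricted model whose probability of
    repeating a food scan is blind to the scan outcome, and an extended model
    that conditions it on whether the last scan found food. Selection emerges
    from resource competition alone; genotypes mutate per gene at birth.
    Includes environment construction and annual renewal, a fast C++ event
    scheduler with energy-based demography and a rescue rule for non-viable
    founder populations, ancestor-lineage tracing, drivers for evolutionary
    runs, ecological genotype comparisons and two-parameter adaptive-landscape
    scans, and trajectory analyses (yearly intake, patch-visit segmentation,
    inter-patch travel, movement summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
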