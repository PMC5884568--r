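Package: drivedyn
Title: Population Dynamics of Two-Locus Underdominance and Killer-Rescue
    Gene Drives
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Deterministic delay-differential-equation models coupling the
    population genetics and population dynamics of two-locus engineered
    underdominance (UD) and killer-rescue (KR) gene drive systems in
    mosquito populations.  Implements the nine-genotype two-locus model
    with density-dependent larval competition, early- or late-acting
    fitness and lethal effects, single-deme and two-deme (migration)
    configurations, release strategies, performance metrics
    (suppression, transgene frequencies, outcome classification),
    threshold extraction by bisection, and a discrete-generation
    population-genetics comparator.  Trajectories, metrics and scan
    grids are returned as tibbles; results have tidy(), glance() and
    autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    callr,
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
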