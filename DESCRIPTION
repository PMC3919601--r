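Package: riborotate
Title: Ribosome Rotational-State Analysis from rRNA Chemical Probing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of ribosome intersubunit rotation from
    rRNA chemical-probing (SHAPE/kethoxal) reactivity data: per-region
    median normalization of integrated peak areas, five-level per-trace
    statistical discretization of reactivities, condition-vs-condition
    difference maps, and a landmark-bridge panel score placing a sample on
    the non-rotated to rotated continuum. Companion analyses cover
    equilibrium ligand binding with ligand depletion (quadratic single-site
    model, Scatchard and competition analyses), single-turnover
    peptidyltransfer kinetics, and dual-luciferase translational-fidelity
    statistics. A synthetic-data generator with known ground truth stands in
    for raw capillary-electrophoresis and filter-binding data.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
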