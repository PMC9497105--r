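Package: nociphys
Title: Quantitative Analysis of Nociceptor-Like Neuron Physiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the functional characterization of stem-cell-derived
    nociceptor-like neurons. Estimates passive membrane properties
    (input/series resistance, whole-cell capacitance) from averaged
    capacitive-transient sweeps, extracts action-potential features
    (half-width, afterhyperpolarization kinetics, repolarization shoulder),
    fits and classifies mechanically-activated currents into rapidly,
    intermediate and slowly adapting classes, calls agonist responders and
    computes sensitization statistics from ratiometric calcium-imaging
    traces, and summarizes bulk RNA-seq count matrices with median-of-ratios
    normalization and marker-relative center-scaled profiles. A synthetic
    data generator with known ground truth supports parameter-recovery
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    signal,
    minpack.lm,
    stats,
    utils,
    generics
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
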