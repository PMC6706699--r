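Package: ccptools
Title: Quantitative Analysis of Clathrin-Coated Pit Dynamics and Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for quantitative TIRF-microscopy analysis of
    clathrin-coated pits (CCPs) and the binding biophysics of their
    regulators. Detects diffraction-limited spots by 2D Gaussian fitting
    with a statistical amplitude test in a master channel and dependently
    in slave channels; normalizes per-cell intensity distributions onto a
    median reference; computes Pearson correlation and equal-count
    proportion-versus-intensity curves for channel pairs; links detections
    into tracks and derives lifetime distributions, bona fide, transient
    and persistent classification, slave-positivity, cohort-averaged
    traces, and sub-sample recruitment-timing estimates; and fits
    single-site anisotropy, biexponential SPR dissociation, 1:1 amplitude
    isotherms, single-site ITC isotherms, and NMR chemical-shift
    perturbations. A synthetic-data module generates movies, stills,
    track tables and titrations with full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    stats,
    minpack.lm,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    generics
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
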