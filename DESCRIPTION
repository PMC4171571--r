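Package: streakcell
Title: Single-Cell Motility, Imaging and qPCR Analysis for
    Primitive-Streak-Like Differentiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for quantifying the behaviour of mouse
    embryonic stem cells differentiating towards a primitive-streak-like
    fate: trajectory motility statistics (instant velocities, mean-squared
    displacement, effective diffusivity over time windows, turning-angle
    persistence), nuclear-intensity quantitative image analysis with
    correlation timecourses, reporter-positive population fractions with
    ANOVA/Tukey condition testing, and kinetic (MAK2) qPCR quantification
    with reference-gene normalization. A synthetic-data module generates
    confined persistent random walks with EMT onset, condition-dependent
    reporter pulses, nuclear image stacks with correlated channels,
    cytometry-like event tables and qPCR amplification curves, so the full
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    graphics,
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
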