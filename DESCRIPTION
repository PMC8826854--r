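Package: pegroot
Title: Modelling Rice Seminal Root Growth Under Graded PEG Osmotic Stress
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying seminal root growth of rice seedlings
    across a consecutive series of polyethylene-glycol (PEG 6000)
    concentrations. Implements a logistic time-course model whose upper
    asymptote (the full seminal root length K) follows a unimodal
    Hoerl-type dose-response over PEG concentration, joint nonlinear
    least-squares estimation of all coefficients from long-format
    observation tables, a synthetic-data generator emulating the
    consecutive-concentration experimental design, image-based
    longest-root-length measurement (binarization, skeletonization and
    skeleton graph diameter), and a command-line pipeline tying the
    stages together.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
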