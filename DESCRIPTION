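Package: fiberstretch
Title: Force-Controlled Cyclic Stretching Rheometry for Soft Hydrogel Microfibers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Desk-scale simulator and analysis toolkit for measuring the
    elastic modulus of soft hydrogel microfibers (e.g. GelMA) by
    force-controlled cyclic stretching. Models the microfiber as a
    standard-linear-solid (SLS) viscoelastic element, fits relaxation
    parameters, realises the plant in state space, and closes the loop with
    a model-reference adaptive force controller (Luenberger observer, LQR
    baseline, Lyapunov adaptive law). Includes an Euler-Bernoulli cantilever
    model of the force-sensing tube with stiffness calibration, synthetic
    microscope imagery with Harris-corner tip detection and a pixel-noise
    model, and downstream small-amplitude oscillatory analysis: sinusoid
    fitting, elliptical Lissajous stress-strain loops, modulus extraction,
    loop-area dissipation, and constant-force ramp comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    minpack.lm,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
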