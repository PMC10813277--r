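Package: implantrom
Title: Parametric Reduced-Order Modelling for Dental Implant Placement Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A toolkit for surrogate-based ("reduced-order model") planning of
    dental implant placement. Defines the six-variable placement design space
    (implant length and diameter, cancellous-bone Young's modulus, front-rear
    and left-right placement angles, cortical-bone thickness), generates
    Taguchi L25 orthogonal-array and full-factorial experimental designs,
    provides a deterministic stress-response emulator anchored to published
    single-factor finite-element sweeps of cortical von Mises stress, fits
    polynomial metamodels with genetic-algorithm basis-subset selection
    scored by cross-validated coefficient of prognosis, ranks design-variable
    influence by relative stress range, and classifies candidate placements
    against a 40 MPa cortical-stress safety threshold in real time.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    tidyr,
    ggplot2,
    generics,
    jsonlite,
    readr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
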