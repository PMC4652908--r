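Package: twostream
Title: Two-Stream Visual Localization Models of Grid-Cell Firing-Field
    Compression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates how two visual localization mechanisms drive grid-cell
    firing in the rodent medial entorhinal cortex, and why their firing fields
    respond differently when arena barriers are moved. A moving feature system
    estimates self-motion from ground-plane optic flow and path-integrates it
    into a location estimate; a static feature system triangulates location
    from the bearings of wall landmarks under a regularized compression model.
    Both estimates feed an oscillatory-interference (velocity controlled
    oscillator) model and a twisted-torus attractor network of grid cells.
    Includes synthetic foraging-trajectory generation with collision
    avoidance, Gaussian noise injection in the angle and angular-velocity
    domains with a domain-independent signal-to-noise measure, Brownian-motion
    error statistics for path integration, spatial rate maps, gridness
    scoring, and a rate-map compression-matching scan.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
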