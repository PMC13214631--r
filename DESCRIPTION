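Package: listingr
Title: Binocular Listing's Law Kinematics for Eyes with Misaligned Optics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A kinematics engine for the binocular formulation of Listing's law
    in a reduced eye model whose optical components are misaligned (the fovea
    displaced from the posterior pole, the crystalline lens tilted from the
    optical axis). Provides exact Rodrigues rotation-vector algebra, the
    construction of the binocular eyes' resting posture from the misalignment
    angles, gaze rotations to fixation targets under selectable conventions,
    the decomposition of any posture change into torsion-free and torsional
    parts, the binocular half-angle rule with displacement planes and
    tilt-angle coefficients, and the noncommutative configuration-space
    algebra of fixation sequences. Tabular interfaces take and return tibbles;
    results have tidy() and autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
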