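Package: learnwalk
Title: Agent-Based Simulation of Multimodal Insect Learning Walks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates the pre-foraging learning walks of ants as an
    agent-based model that fuses three navigation cues: visual familiarity
    from a mushroom-body (VPN-KC-MBON) memory of rotation-invariant
    Zernike-moment panorama encodings, innate chemotaxis on a nest-centred
    Gaussian odour field, and noisy path integration.  A dynamically
    weighted Homing Vector is rotated by a familiarity-driven offset into a
    Learning Vector that balances exploration against safe return.  The
    package generates its own synthetic 3D terrain, runs multi-walk
    learning protocols and displacement homing tests, and provides
    trajectory metrics (convex-hull coverage, maximum excursion, turning
    statistics), cue-weight analyses, species-variant comparisons, and a
    paired-statistics pipeline with Holm correction and effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
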