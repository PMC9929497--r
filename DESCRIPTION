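Package: flockwake
Title: Fuzzy Characterization of In-Wake Flight in Bird Line Formations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to detect and analyse in-wake (upwash-exploiting) flight in
    bird flocks flying in line or V formations from high-rate 3D trajectory
    data. Absolute flock trajectories are transformed into leader-relative
    coordinates via heading smoothing, translation and rotation; every ordered
    dyad is then scored with a knowledge-based zero-order Takagi-Sugeno fuzzy
    inference system that models the wingtip-vortex upwash region (lateral
    alignment, anteroposterior distance, co-planarity), and each bird is
    assigned at most one wake provider per snapshot. Includes a frontal
    nearest-neighbour baseline, flock-level analytics (bouts, alone time,
    leader preference with bootstrap null intervals, formation subgroups via
    weakly connected components, model agreement), and a synthetic flock
    simulator with planted ground truth for end-to-end validation.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
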