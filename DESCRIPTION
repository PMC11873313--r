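Package: stsa
Title: Spatiotemporal Survival Analysis of Movement-Trajectory Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Distributional analysis of two-alternative forced-choice
    responses recorded as continuous movement trajectories (for example
    hand paths in a virtual-reality N-back task). Implements discrete-time
    survival analysis of completed response times (hazard, survivor and
    conditional-accuracy functions, interpolated median RT, display
    masking), spatiotemporal survival analysis of first-crossing events
    over incremental spatial thresholds (hazard and conditional-accuracy
    heat maps, occupancy grids), the classical comparison chain (outlier
    trimming, variance diagnostics, repeated-measures ANOVA with
    Greenhouse-Geisser correction, paired post-hoc contrasts, windowed
    conditional-accuracy inference), and a synthetic trajectory generator
    with known ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
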