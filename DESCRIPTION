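Package: tagrid
Title: Satellite-Hybrid Reconstruction of Daily Air Temperature on a 1 km Grid
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Reconstructs daily minimum, mean, and maximum near-surface air
    temperature on a 1 km sinusoidal grid from weather-station records and
    satellite land-surface temperature (LST). Provides a quality-assessment
    cascade for heterogeneous (including crowdsourced) station networks, a
    two-satellite LST merge with within-year temporal gap-filling, per-year
    linear mixed-effects calibration with day-specific random intercepts and
    LST slopes, station-holdout cross-validation with spatially weighted
    error metrics, and extreme-temperature person-day exposure surfaces.
    A synthetic-data module generates fully labelled test regions so the
    entire pipeline runs without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    geosphere,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
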