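Package: boundedwalk
Title: Bounded Random Walks and Boundary-Bias Correction for Intermittent
    Locomotion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Null models of intermittent locomotion as uncorrelated random
    walks confined to bounded convex domains (intervals, convex polygons,
    disks) under no-go, stop-go and reflecting boundary conditions.
    Provides seeded ensemble simulation of stopping-location sequences,
    steady-state stopping densities (closed forms and a Nystrom/power
    iteration solver for the stationary Fredholm problem),
    geometry-specific shaper functions (the set covariance of the domain),
    transformed step densities, and reconstruction of the intrinsic step
    distribution from boundary-biased empirical step histograms with
    ensemble uncertainty envelopes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
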