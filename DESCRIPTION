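Package: crowdprox
Title: Pedestrian Crowding and Social Distancing Violations from
    Ground-Plane Detections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how pedestrian crowding drives violations of
    interpersonal distancing rules in public space.  Generates synthetic
    ground-plane pedestrian detections with realistic crowd-size and
    grouping structure, scores per-person and per-frame proximity
    violations at a configurable distance threshold, fits linear
    probability models with cluster-robust standard errors (optionally
    with camera fixed effects), frame-level least squares, binned
    scatterplots, Tukey outer-fence winsorizing and Krippendorff's alpha,
    and contrasts observed contact counts against a random-placement null
    model that separates geometric necessity from behavioural attraction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    rlang,
    withr,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    jsonlite,
    optparse
Config/testthat/edition: 3
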