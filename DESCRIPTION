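Package: duokrig
Title: Dual-Instrument Geostatistical Mapping of Soil Contaminants
Version: 0.1.0
Authors@R:
    person("Analytics", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for mapping soil trace-element concentrations (e.g. Cu, Pb)
    from surveys that combine a sparse, accurate laboratory assay (ICP-AES-like)
    with a dense, biased field assay (PXRF-like). Implements experimental and
    model variograms with geometric anisotropy, ordinary kriging, lognormal
    kriging, ordinary co-kriging under a linear model of coregionalization,
    linear inter-instrument calibration with primary-preference data fusion,
    leave-one-out and holdout validation, and a synthetic dual-instrument
    survey generator for desk-scale benchmarking of the four mapping
    strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
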