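Package: cfcalcium
Title: Analysis and Simulation of Climbing-Fiber Calcium Events in Purkinje Cell Dendrites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing dendritic calcium signals recorded from
    cerebellar Purkinje cells with two-photon imaging, focused on
    climbing-fiber (CF) triggered calcium events and how their probability,
    latency, population synchrony and size encode the strength of a
    periocular stimulus. Provides percentile-baseline dF/F computation,
    template-based two-step event detection, spontaneous/evoked
    classification, onset-latency estimation, per-dendrite probability
    coding and categorisation, pairwise joint-probability and
    extra-synchrony statistics, event-size (dF/F-integral) quantification
    with a jitter-matched spontaneous reference, and extraction of the
    slow non-CF calcium component. A calibrated synthetic-data generator
    renders ground-truth CF activity to fluorescence traces and pixel
    movies so that every stage of the pipeline can be validated by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
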