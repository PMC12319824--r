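Package: statecpm
Title: Phase-Synchrony Dynamic Connectivity and Predictive Modeling of Brain States
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies behaviorally relevant brain states from parcellated fMRI
    time series. Computes phase coherence-based dynamic functional connectivity at
    single-frame resolution via the analytic (Hilbert) signal, averages it over
    sliding or event-centered windows, and feeds the windowed edge vectors into
    connectome-based predictive models (CPM) of a subject trait or a time-varying
    in-scanner behavior. Models are validated against within-scan temporal-shuffle
    and resting-state null conditions, and distilled by resample aggregation of
    split-half cross-validation folds into frequency-thresholded, temporally
    specific state models with per-timepoint performance profiles. Includes a
    synthetic multi-subject cohort generator with planted, behavior-coupled
    phase-locking episodes so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
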