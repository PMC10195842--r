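Package: spikespread
Title: Subset Training of Balanced Spiking Networks and Analysis of Activity Spread
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates strongly coupled excitatory-inhibitory spiking networks in
    the balanced regime and trains the synaptic inputs of a selected subset of
    neurons with a regularized recursive-least-squares (FORCE-style) rule acting
    on sparse plastic synapses. Provides target generation (random-phase
    sinusoids, conversion of firing-rate PSTHs to input targets through the
    Ricciardi transfer function, and a parametric generator of cortical-like
    low-dimensional PSTHs), population analyses (PSTH estimation, PCA, shared
    variance, choice selectivity, coding-mode projections, perturbation recovery
    times, spiking statistics), and closed-form mean-field predictions for how
    trained activity spreads to untrained neurons through task-independent
    strong synapses, including a weak-coupling control construction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    utils,
    tools,
    pracma,
    nortest,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
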