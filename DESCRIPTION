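Package: wmpulse
Title: Synthetic-EEG Analysis of spTMS Effects on Working-Memory Priority
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates multichannel EEG-like recordings from a double-serial
    retrocue working-memory experiment with single-pulse TMS (spTMS) and known
    ground truth (von Mises phase resets, category-specific band-power
    patterns, delay-period power decay), and re-implements the analysis chain
    such experiments use: TMS artifact-gap interpolation and numeric
    preprocessing, Hanning-window time-frequency decomposition and band-power
    feature assembly, L2-logistic presence/absence decoding with nested
    z-scoring and AUC aggregation, cluster-based permutation inference,
    Hilbert-phase measures of event-related phase reorganization with
    frequency-adaptive window selection, relative band-power dynamics, and the
    supporting circular, rank-based and power-analysis statistics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
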