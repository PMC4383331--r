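Package: tffo
Title: Time-Frequency Feature Optimization for Single-Electrode EEG
    Discrimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discriminates two subject populations (e.g. schizophrenia
    patients and healthy controls) from short, stimulus-locked EEG
    segments recorded at a single electrode.  Implements the TFFO
    pipeline: band-pass filtering and energy normalization, ICA-based
    blink removal, epoching with miss/saccade/amplitude exclusion rules,
    the discrete Stockwell time-frequency transform, windowed feature
    extraction, k-nearest-neighbour leave-one-out classification with a
    distance score, exhaustive optimization over electrode, time window,
    frequency band, event count and neighbour count, disease-severity
    ridge regression on the distance to the healthy centroid, and
    latency-based baseline classifiers.  Includes a synthetic two-group
    ERP cohort generator with 1/f background noise, Gabor-burst evoked
    responses, habituation, and injectable blink/saccade/miss/amplitude
    artifacts so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
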