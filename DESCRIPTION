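Package: crossFC
Title: Cross-Species Functional Connectivity Fingerprinting
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Seed-based resting-state functional connectivity fingerprinting
    for cross-species comparison. Computes seed correlation maps from 4D BOLD
    volumes or region-level time series, builds interareal connectivity
    fingerprints over a canonical set of eight target regions, min-max
    normalizes them, compares seed sets across species by cosine similarity,
    and assesses fingerprint differences with a scan-level permutation test
    using a lowest-first-percentile decision rule. Includes a synthetic
    resting-state data generator with planted connectivity structure and
    AR(1) temporal noise so the full pipeline is testable without
    acquisition data, plus the in-scope preprocessing tail: Gaussian spatial
    smoothing, nuisance regression of confounds, and zero-phase Butterworth
    temporal band-pass filtering.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
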