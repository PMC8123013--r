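Package: nuecg
Title: Diagnostic Interpretation of Non-Uniformly Sampled Electrocardiograms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for storing, producing and diagnostically interpreting
    non-uniformly sampled ECG records. Provides an arbitrary wave-border-anchored
    resampling model (standardized local bandwidth, 100-500 Hz), a
    sampling-grid-independent QRS detector built from kernel-regression slope
    angles, a graph-distance multipass heartbeat classifier, a non-uniform to
    time-scale (NUTS) transform by slotted correlation with Coiflet-5 atoms with
    P/QRS/T wave delineation, the associated evaluation metrics (PRD, Se/PPV/Fd,
    weighted diagnostic distortion), and a deterministic synthetic multilead ECG
    generator with ground-truth annotations for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
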