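Package: trflptools
Title: Alignment, Normalization and Comparison of T-RFLP Community
    Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Processing of terminal restriction fragment length
    polymorphism (T-RFLP) peak tables exported from capillary
    electrophoresis genotyping software: peak detection thresholding,
    moving-average alignment binning with ambiguity classification,
    detection and correction of systematic shifts in fragment size
    estimation, iterative total-fluorescence and fixed-percentage
    threshold normalization, consensus profile construction, and Jaccard
    and Bray-Curtis similarity matrices for community comparison. A
    synthetic profile simulator with a calibrated noise model (size
    estimation jitter, per-profile systematic shifts, loading-dependent
    total fluorescence, baseline artifact peaks) supports method
    evaluation and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
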