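Package: octskin
Title: Skin Surface Roughness and Optical Metrics from OCT Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies skin surface texture from three-dimensional optical
    coherence tomography (OCT) volumes. Segments the air-skin boundary in each
    B-scan (a deterministic adaptive-threshold backend and a small trainable
    encoder-decoder network), removes the natural curvature of the skin by
    per-B-scan second-order least-squares fitting, and computes the ISO-style
    arithmetic mean roughness (Ra) and depth of roughness (Rz) on the flattened
    three-dimensional boundary map. Also estimates epidermal thickness from the
    first peak-valley interval of the depth-resolved mean signal and the dermal
    attenuation coefficient from a log-linear fit. Includes a synthetic layered
    speckle phantom simulator with exact ground truth so that every stage of
    the pipeline can be validated against analytic values, plus volume I/O
    (multi-page TIFF with JSON sidecars), an end-to-end pipeline driver, and a
    cohort correlation analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tiff,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
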