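Package: pushbroom
Title: Pushbroom Hyperspectral Laparoscopy: Calibration, Cube Assembly,
    Tissue Indices and System Characterization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data-processing chain for a pushbroom (line-scanning)
    hyperspectral laparoscope, together with a synthetic scanner so every
    stage can be exercised without hardware. Covers spectrograph wavelength
    calibration and channel binning, dark/white reflectance balancing and
    absorbance conversion, streaming assembly of hyperspectral cubes with
    ENVI-style input/output, the organ hemoglobin index with false-color
    rendering, robust homography estimation (RANSAC) for overlaying
    spectral maps on the color-video frame, and system characterization:
    signal-to-noise maps, illumination spot and distance falloff, and
    Michelson-contrast spatial resolution on bar targets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    jsonlite,
    yaml,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
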