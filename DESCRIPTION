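Package: vitalmaps
Title: Spatio-Temporal and Spectral Feature Maps for Camera-Based Vital-Sign Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Compresses the dynamic content of monochrome video segments from
    photoplethysmography imaging (PPGI) and infrared thermography (IRT) into
    spatio-temporal and spatio-spectral feature maps. Frames are spatially
    pooled with a Gaussian kernel and decimated to a region-of-interest
    lattice; each lattice pixel series is mean-removed, bandpass filtered with
    a zero-phase Butterworth filter, Hann windowed and transformed to a scaled
    power spectrum, from which a bank of twenty per-pixel features (band
    powers, spectral moments and shape descriptors, peak frequency and phasor,
    temporal variance, spectral fluxes) is assembled into maps. Postprocessing
    provides decibel conversion, normalization and quantization, histogram
    intersection similarity maps against a background model, and RMS-contrast
    evaluation of labeled regions. A deterministic synthetic scene generator
    emulates pulsatile foregrounds, distinct-frequency sub-regions, specular
    reflections, illumination flicker and cast shadows for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    tiff,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
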