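Package: zeobench
Title: Lanthanide-Zeolite Thin-Film Model System for Benchmarking
    Fluorescence Bioimaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and analysis tools for a reproducible fluorescence
    microscopy benchmark: lanthanide(III)-doped Linde Type A zeolites
    dispersed in a dye-stained polyvinyl-alcohol thin film, imaged by
    raster-scanned hyperspectral confocal microscopy.  Provides per-pixel
    emission-spectrum cubes, neon-lamp wavelength calibration, virtual
    bandpass filter-channel extraction, two-pixel background-subtracted
    signal estimates, fluorophore brightness and photon-budget arithmetic,
    cross-excitation and emission bleed-through matrices, and photobleaching
    trace construction with bi-exponential decay fitting.  A seeded
    synthetic-scene generator emulates the full model system so every stage
    is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
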