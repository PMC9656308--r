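Package: microvflow
Title: Quantitative Post-Processing of Microvascular Doppler Ultrasound Captures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to turn color-coded microvascular Doppler (MicroV)
    ultrasound captures into quantitative 8-bit flow-intensity maps and
    first-order radiomic feature tables. Builds inverse look-up tables (LUTs)
    from a machine's displayed color scale, retro-converts RGB captures to
    flow intensity by nearest-color matching, passes grayscale (MV2) captures
    through unchanged, computes rectangular-ROI first-order statistics and
    histograms, and generates synthetic vascular phantoms with known ground
    truth so the whole pipeline can be validated end to end without clinical
    images. Reads DICOM secondary captures, TIFF and PNG; writes TIFF, CSV
    and JSON.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
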