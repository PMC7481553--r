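Package: lfaquant
Title: Quantification and Calibration of Lateral Flow Assay Strip Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Densitometric readout and calibration analysis for lateral flow
    (immuno)assay strip images. Reads single-channel strip photographs
    (8/16-bit PNG and TIFF, grayscale or RGB), crops and splits batch images
    into lanes, extracts flow-axis intensity profiles, localises up to six
    bands per lane and computes Otsu-background-corrected band AUC values.
    Band intensities are merged with an experiment design table, technical
    replicates are averaged, linear calibration curves are fitted per analyte
    and channel, and the key measures limit of blank (LOB), limit of
    detection (LOD) and limit of quantification (LOQ) are derived in
    concentration units by inverse prediction. Includes a ground-truthed
    synthetic strip-image simulator for duplex (two-channel) experiments, a
    deterministic HTML/Markdown report generator and a command-line workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    png,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
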