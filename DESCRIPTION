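Package: treefusion
Title: Two-Stage Multi-Sensor Fusion for Individual Tree Taxon Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies individual tree crowns to species or genus by fusing
    three airborne remote-sensing data streams: high-resolution RGB
    orthoimagery, imaging-spectrometer reflectance (426 bands, 380-2505 nm),
    and discrete-return lidar point clouds. A convolutional network scores
    crown image chips, crown-centroid reflectance spectra are cleaned of
    water-absorption bad bands, and lidar returns are summarized as vertical
    pseudo-waveforms; a shallow fusion network trained with a differentiable
    soft F1 loss combines the three blocks and an open-set post-processing
    step diverts low-confidence predictions to an "Other" class. Includes a
    synthetic multi-sensor scene generator emulating NEON-style 20 m plot
    products so the full pipeline is testable end to end, plus competition
    style evaluation reports (confusion matrices, per-class and averaged F1,
    accuracy, cross-entropy).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
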