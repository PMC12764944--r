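Package: dichropam
Title: Dichroism-Sensitive Photoacoustic Image Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis toolkit for polarization-resolved (dichroism-sensitive)
    photoacoustic microscopy. Reconstructs maximum-amplitude-projection images
    from A-line volumes, applies per-state laser-fluence normalization, maps
    the degree and orientation angle of linear dichroism (DoLD, AoLD) from
    Stokes parameters of four-angle image stacks, and summarises tissue
    alignment with axial circular statistics (resultant vector length, mean
    angle with bootstrap confidence intervals, polar histograms). Includes a
    structure-tensor orientation estimator for fluorescence micrographs, an
    optical-mapping module for voltage-dye movies (F/F0 normalization and
    per-pixel activation times), and a synthetic fibrous-phantom generator
    with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    tibble,
    generics,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
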