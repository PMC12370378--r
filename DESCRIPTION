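Package: qsmfid
Title: Gold Fiducial Marker Detection in Prostate MRI by Quantitative
    Susceptibility Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reconstruction pipeline that localizes implanted gold fiducial
    markers in multi-echo T2*-weighted gradient-echo MRI of the prostate via
    quantitative susceptibility mapping (QSM): nonlinear complex field-map
    fitting, Laplacian phase unwrapping, background field removal by
    projection onto the dipole field, zero-referenced regularized dipole
    inversion, and susceptibility-based candidate classification that
    separates gold markers from calcifications and air pockets.  Includes a
    digital pelvis phantom simulator with partial-volume rasterization and
    static-dephasing signal voids, rigid frame-coordinate calibration from
    MR-visible rods, and detection/image-agreement metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
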