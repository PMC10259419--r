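Package: scatterfiber
Title: Nerve Fiber Orientations from Scattered Light and X-Ray Scattering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for scattering-based nerve fiber orientation
    mapping in brain sections. Extracts cyclic azimuthal intensity profiles
    from scattered light imaging (SLI) stacks, SLI scatterometry patterns,
    small-angle X-ray scattering (SAXS) detector frames, and fiber
    orientation distributions (FOD) sampled in the section plane; detects
    azimuthal peaks with prominence filtering and sub-bin refinement; pairs
    peaks into up to three in-plane axial fiber orientations per pixel;
    relates SLI peak distance to out-of-plane fiber inclination through a
    pluggable calibration curve; and compares orientation maps across
    modalities with crossing-aware angular differences, multiplicity
    statistics, and peak-distance-versus-inclination tables. A synthetic
    phantom generator renders ground-truth fiber configurations into all
    modalities for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    pracma,
    yaml,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
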