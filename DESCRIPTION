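Package: cstetQuant
Title: Quantitative Density Calibration and Granule Morphometry for
    Cryo-STEM Tomograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts bright-field cryo-STEM tomogram intensities into
    absolute material densities using internal standards. Builds per-element
    atom number densities for reference materials (ribosomes, ribosomal RNA,
    crystalline tricalcium phosphate, vitreous ice), predicts bright-field
    scattering signals per unit volume from partial elastic cross-sections,
    calibrates the additive unscattered background from ribosome/water
    intensity ratios, and maps tomogram intensities to fraction-of-TCP, mass
    density and equivalent molar ion concentrations. Includes threshold-based
    3D granule segmentation and morphometry (size distributions, volume
    fractions), Fourier band-pass preprocessing, MRC volume I/O, and a
    synthetic tomogram generator with a toy parallel-beam tilt projector and
    WBP/SIRT reconstructions for end-to-end validation by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
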