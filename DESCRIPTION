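Package: rascv
Title: Correction-Vector Restricted-Active-Space Simulation of L-Edge XAS
    and 2p3d RIXS Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates L2,3-edge X-ray absorption (XAS) and 2p3d resonant
    inelastic X-ray scattering (RIXS) spectra of open-shell transition-metal
    complexes with a restricted-active-space (RAS) configuration-interaction
    ansatz that includes mean-field Breit-Pauli spin-orbit coupling.  Spectra
    are computed from frequency-dependent correction vectors (shifted linear
    systems) rather than explicit sums over excited states; a dense
    sum-over-states reference path is provided for verification.  The package
    also implements particle-hole and Loewdin spin-projection deconvolution of
    the spectra, a ligand-field model generator for 2p-3d multiplet physics,
    and reader/writer support for an extended FCIDUMP integral format carrying
    spin-orbit and dipole one-body matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    methods,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
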