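Package: ulfdwi
Title: Simulation and Analysis of Ultra-Low-Field Diffusion MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying diffusion MRI at ultra-low magnetic field
    strength (tens of mT). Simulates multi-shot fast-spin-echo diffusion
    acquisitions on digital fibre phantoms with the artifact physics that
    dominates this regime (spatially varying diffusion encoding from a static
    background field gradient, multiplicative B1 bias, echo-train-length
    dependent point-spread-function blur, Rician noise), implements the
    corresponding retrospective corrections, and analyses the corrected data
    with weighted least-squares and robust (RESTORE) diffusion tensor fitting,
    constrained spherical deconvolution at low harmonic order, anatomically
    constrained streamline tractography, and quantitative recovery metrics
    against the phantom ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
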