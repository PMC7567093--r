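Package: bctsim
Title: Dose-Constrained Simulation and CNR Optimization for Propagation-Based Breast CT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analytical simulation and analysis chain for monochromatic
    parallel-beam breast computed tomography. Builds cylindrical two-material
    and breast-like software phantoms, converts a prescribed mean glandular
    dose into per-projection photon fluence through a normalized-glandular-dose
    model, simulates photon-counting projections with Poisson statistics,
    applies single-material TIE-Hom (Paganin) phase retrieval, reconstructs
    with Shepp-Logan filtered back-projection, and measures
    glandular-to-adipose contrast-to-noise ratio as a function of beam energy
    and dose, including photon-starvation diagnostics and step-wedge
    attenuation-coefficient fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    tiff,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
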