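Package: nanotarget
Title: Spatiotemporal Modelling of Sequential Antiangiogenic and
    Chemotherapeutic Delivery by Nanocells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Coupled reaction-diffusion modelling of tumour growth, tumour
    vasculature, and nanoparticle-mediated drug delivery.  Implements a
    Fisher-KPP tumour-cell field coupled to a cubic vessel-density field,
    carrier (liposome/nanocell) uptake limited by vascular efficiency,
    gamma-kernel drug-release profiles normalised over a dosing schedule,
    and the pharmacodynamics of a fast-released antiangiogenic agent
    (combretastatin) combined with a slowly released chemotherapeutic
    (doxorubicin).  Provides fixed-point analysis of the homogeneous
    system, an explicit finite-difference simulator on a 3D no-flux grid,
    treatment-arm comparison, parameter calibration against tumour-volume
    curves, single-parameter sensitivity scans, and a synthetic
    volume-curve generator for end-to-end parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
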