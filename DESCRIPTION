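Package: atriawave
Title: Kinetic IKur Block and Rotor Dynamics in Remodeled Human Atrial Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Mechanistic simulator and analysis pipeline for chronic atrial
    fibrillation pharmacology. Implements the Courtemanche-Ramirez-Nattel human
    atrial myocyte model with a chronic-AF electrical-remodeling variant, state-
    dependent (time- and voltage-dependent) block of the ultra-rapid delayed
    rectifier current IKur, an explicit monodomain reaction-diffusion solver on
    1D strands and 2D sheets, restitution protocols (APD, ERP, CV, wavelength,
    alternans, minimum diastolic interval), and fibrillation analysis: percent
    refractory area, pseudo-ECG dominant frequency, phase-singularity detection
    and spiral-tip trajectory tracking. Includes analytic synthetic fixtures
    (spiral movies, figure-of-eight pairs, multi-tone traces) so every analysis
    stage is testable without tissue simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
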