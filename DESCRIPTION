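Package: cdfit
Title: Correlation-Driven Density Fitting for Cryo-EM Structure Refinement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Flexible fitting of atomic models into cryo-EM density maps by
    maximizing the real-space correlation between the experimental map and a
    Gaussian-simulated model density. Provides the correlation biasing
    potential with exact analytic forces, adaptive-resolution and
    force-constant schedules with simulated annealing, Fourier shell
    correlation (FSC) cross-validation against half-maps to detect
    overfitting, MRC/CCP4 map input/output, a minimal bonded force field and
    Langevin integrator for desk-scale refinement experiments, synthetic
    fixture generation (toy polymers, ground-truth maps, half-map pairs),
    and validation statistics (Kabsch superposition RMSD, per-residue
    outlier propensities).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
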