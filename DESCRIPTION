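Package: chromodyn
Title: Chromatin Mobility, Polymer Dynamics and Hi-C Contact Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying interphase chromatin dynamics from
    single-particle tracking and chromosome conformation capture data.
    Implements per-track mean squared displacement (MSD) curves with an
    exact weighted ensemble mean and standard error, two-stage power-law
    fits of anomalous-diffusion exponents, weighted kernel-density and
    Gaussian-mixture summaries of exponent distributions, and the length
    of constraint of a tracked locus.  Includes a coarse-grained
    bead-spring (Rouse) polymer simulator with optional excluded volume
    and spherical confinement, the analytic monomer MSD scaling
    predictions for ideal and excluded-volume chains, and Hi-C
    contact-matrix statistics: matrix balancing, contact classification,
    distance-decay curves, band z-score loop calling, aggregate peak
    matrices, insulation vectors, border profiles and virtual 4C.
    Synthetic-data generators with known ground truth (fractional
    Gaussian motion trajectories, Ornstein-Uhlenbeck confined tracks,
    and contact maps with planted loops and domains) make every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    minpack.lm,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
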