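Package: naso3d
Title: 3D Anthropometry of the Nasolabial Region on Triangle Meshes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Measurement engine for 3D surface anthropometry of the
    nasolabial region in infants. Reads triangle meshes (PLY, OBJ, STL)
    and named anatomical landmark sets, and computes a battery of 84
    parameters: 32 direct or perpendicular distances, 32 on-surface
    (geodesic) curves, 2 angles and 18 dimensionless indices, together
    with alar-base type classification from landmark laterality.
    Includes the reference-database statistics layer (per-sex growth
    curves with prediction and z-scores, two-way intraclass correlation
    coefficients, tolerance-based percentage agreement, and
    chained-equations predictive-mean-matching imputation) and synthetic
    generators for analytic geodesic fixtures, parametric faces with
    ground-truth landmarks, and simulated cohorts.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
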