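Package: dmta
Title: Dental Microwear Texture Analysis of Gridded Tooth Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dental microwear texture analysis (DMTA) of gridded
    3D tooth-surface height maps. Reads and writes Digital-Surf-style .sur,
    ASCII matrix and XYZ height maps; reconstructs scale-limited roughness
    surfaces (void restoration, despiking, polynomial form removal, areal
    spline/Gaussian filtration); computes 23 ISO 25178-2 areal texture
    parameters including height, material-ratio, spatial, hybrid and feature
    parameters; and runs a multi-stage dietary-discrimination analysis
    (variance-gated classic/Welch ANOVA, Benjamini-Hochberg false discovery
    control, Tukey HSD, correlation-mode principal components with projection
    of unknown specimens, Spearman rank correlation and subsampling
    robustness). A synthetic wear-surface generator produces analytic oracle
    surfaces and stochastic cohorts with scratch and pit features whose
    density and depth encode an ordinal diet level.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
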