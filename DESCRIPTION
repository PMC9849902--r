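Package: FaceTrust
Title: Facial Sexual Dimorphism and Trust-Game Behavior
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for linking landmark-based facial shape to behavior in
    binary-choice Trust Games. Implements two-dimensional geometric
    morphometrics (TPS file input, Generalized Procrustes superimposition
    with sliding semi-landmarks under the minimum bending-energy criterion,
    thin-plate-spline deformation grids, distance-based permutation MANOVA,
    inter-observer repeatability, and discriminant femininity shape scores
    with within-group z-standardization), Trust-Game behavioral statistics
    (payoff settlement, anonymous-versus-personalized switch and shift
    measures, per-stimulus summaries, Fleiss' kappa consistency), repeated-
    measures regression via generalized estimating equations with robust
    sandwich variance, model-II major-axis regression, and a synthetic-data
    generator with known ground truth so that every stage of the pipeline
    can be validated without access to the original study data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, yaml, jsonlite
Suggests: testthat (>= 3.0.0), MASS, vegan, withr, knitr, rmarkdown
biocViews: Morphometrics, StatisticalMethod, Visualization
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'FaceTrust-package.R'
    'femininity.R'
    'gee.R'
    'inference.R'
    'manova.R'
    'pipeline.R'
    'procrustes.R'
    'scheme.R'
    'simulate-behavior.R'
    'simulate-faces.R'
    'tps-io.R'
    'tps-spline.R'
    'trust-game.R'
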