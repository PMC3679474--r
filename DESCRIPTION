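Package: lungmorph
Title: Automated Lung Morphometry, Respiratory Mechanics and Expression
    Analysis for Murine Emphysema Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis chain for cigarette-smoke and dietary
    emphysema models in mice: automated mean linear intercept (L_M)
    morphometry of H&E parenchyma images (two-class K-means airspace
    segmentation, small-component exclusion, horizontal line-grid
    intercept counting), forced-oscillation mechanics model fitting
    (single-compartment equation of motion, Hantos constant-phase
    impedance, Salazar-Knowles pressure-volume metrics), housekeeping
    normalized qPCR relative expression and protease/antiprotease
    ratios, and the 2x2 factorial inference layer (two-way ANOVA with
    Bonferroni-adjusted planned comparisons, Kruskal-Wallis on binarized
    pathology scores). A synthetic-cohort generator with known ground
    truth exercises every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    car,
    minpack.lm,
    png,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
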