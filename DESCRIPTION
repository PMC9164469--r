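Package: specsens
Title: Performance Assessment of Spectral Classification Models by
    Experimental Training-Data Manipulation
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to assess the performance and robustness of optical
    (hyperspectral reflectance) classification models, with crop-seed
    germination classification as the motivating application.  Provides
    three controlled manipulations of a labeled training set -- class
    assignment error injection, bounded stochastic spectral noise, and
    balanced training-set reduction -- evaluated through ten-fold
    cross-validated accuracy curves, linear regression diagnostics,
    paired t-test comparisons of classifier families (linear
    discriminant analysis and a linear support vector machine), a
    parsimony guard against over-fitting, and sample-level validation
    of predicted germination percentages by RMSE.  A seeded synthetic
    seed-spectra generator with the statistical structure of real
    multi-lot seed data makes the full pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    data.table,
    jsonlite,
    optparse,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    quadprog,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
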