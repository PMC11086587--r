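Package: formtypic
Title: Affective Form Typicality of Word Forms in Spanish-Like Lexicons
Version: 0.1.0
Authors@R:
    person("formtypic", "maintainers", email = "maintainers@formtypic.org",
           role = c("aut", "cre"))
Description: Tools for quantifying sound symbolism in affective word norms:
    articulatory-feature coding of phonemic transcriptions into form-variable
    vectors, rating-agreement and part-of-speech filtering, best-subset
    regression with repeated k-fold cross-validated model selection,
    heteroscedasticity-robust linear fits, per-word z-scored form-typicality
    scores, and the downstream group statistics (Bartlett, Welch ANOVA with
    omega-squared, Games-Howell post hoc, Spearman matrices, hierarchical
    robust regressions with delta-R-squared). Includes a synthetic lexicon
    generator with a multi-rater affect model and planted form-affect
    structure, so the full pipeline is testable without external norms.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
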