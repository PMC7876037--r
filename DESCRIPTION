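Package: trialterm
Title: Clinical Trial Termination Analysis with Rank-Aggregated Feature
    Selection and Undersampling Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying premature termination of registered clinical
    trials. Parses ClinicalTrials.gov-style study records from XML, applies a
    reproducible cohort inclusion filter, and engineers three feature families
    per trial: 40 statistics features (administrative, study information,
    study design and eligibility-text counts), 500 TF-IDF keyword features,
    and 100 dense paragraph-vector embedding features learned from the
    detailed description field. Termination-associated factors are ranked by
    five filter selectors (ANOVA F, mutual information, ReliefF, CIFE, ICAP)
    fused with Dowdall rank aggregation, and termination is predicted with
    random-undersampling ensembles of neural network, random forest, gradient
    boosted tree or logistic regression base learners. Includes the matching
    evaluation battery (accuracy, balanced accuracy, F1, AUC, corrected
    resampled t-test, Holm-Bonferroni, Friedman and Nemenyi critical
    differences) and a synthetic-cohort generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Rcpp,
    nnet,
    ranger,
    stats,
    utils,
    xgboost,
    xml2
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
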