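Package: bedfx
Title: Multi-Fraction Biologically Effective Dose Modelling for Gamma Knife
    Radiosurgery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fraction-resolved biologically effective dose (BED) computation
    for Gamma Knife radiosurgery under a biexponential sublethal-damage repair
    model, with pathology-specific synthetic cohort simulators (arteriovenous
    malformation, vestibular schwannoma, brain metastasis, meningioma), a
    machine-learning layer comparing physical-dose and BED-based outcome
    predictors, Bayesian recovery of the alpha/beta ratio from binary
    outcomes, a neural-network surrogate of the BED engine, and monotone
    logistic planning curves across fractionation schemes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    xgboost,
    randomForest,
    coda,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
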