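Package: msitvc
Title: Neuro-Fuzzy Prediction of Total Viable Counts from Multispectral
    Meat-Spoilage Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for predicting the total viable count (TVC, log10 cfu
    per square centimetre) of bacteria on meat surfaces from 18-waveband
    multispectral reflectance signatures.  Provides a synthetic
    spoilage-data generator built on Baranyi-Roberts growth kinetics,
    ensemble wavelength selection by majority-vote fusion of seven
    ranking methods, a clustering-initialised Takagi-Sugeno neuro-fuzzy
    regressor with asymmetric Gaussian membership functions trained by
    hybrid recursive least squares and gradient descent, stacked
    ensembling of the mean- and standard-deviation-feature models with a
    degree-4 NIPALS meta-model, and the food-microbiology validation
    metrics suite (bias and accuracy factors, RPD, RER, RPIQ and
    companions).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    glmnet,
    randomForest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071
Config/testthat/edition: 3
RoxygenNote: 7.3.3
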