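Package: oilalarm
Title: Two-Stage Alarm System for Edible-Oil Food Safety from B2B
    E-Invoices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Screens business-to-business e-invoice streams of edible-oil
    manufacturers for food-safety risk in two stages: (1) a text sieve
    that classifies merchandise item names as edible-oil-related or not,
    using TF-IDF latent-semantic topic features or expert keyword
    features with k-nearest-neighbour, linear SVM, logistic, neural
    network or random-forest backends; and (2) an anomaly stage that
    aggregates sieved invoices into monthly purchase and sales totals,
    smooths them with a 3-month moving average, derives log
    turnover-ratio features, and flags manufacturer months whose sales
    exceed purchases by an implausible factor via a naive threshold rule,
    bivariate-normal prediction ellipses, or the same classifier
    backends. Includes a reproducible synthetic-data generator emulating
    the statistical structure of a restricted national e-invoice corpus,
    so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    class,
    e1071,
    jsonlite,
    MASS,
    nnet,
    randomForest,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
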