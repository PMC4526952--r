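Package: tweetdbn
Title: Semi-Supervised Deep Belief Network Analysis of Health-Topic Tweet Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A desk-scale pipeline for characterizing a health topic (the
    running example is antibiotics) on Twitter: keyword filtering of JSON
    Lines tweet archives, corpus analytics (daily volume, Z-score spike
    detection, hashtag, retweet and user-concentration statistics),
    multi-rater label adjudication with Fleiss' kappa, bag-of-stems feature
    engineering with an English Snowball (Porter2) stemmer, a semi-supervised
    deep belief network classifier (stacked Bernoulli restricted Boltzmann
    machines pretrained by contrastive divergence, then fine-tuned with
    back-propagation and dropout), stratified cross-validated evaluation
    (accuracy, per-class ROC/AUC, precision-recall break-even), and
    threshold-based category retrieval. Includes a seeded synthetic tweet
    generator so the whole workflow is testable without any corpus download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    tibble,
    dplyr,
    stats,
    utils,
    withr,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
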