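Package: affectpanel
Title: Lexicon-Based Affect Scoring and Moderated Regression for Daily Social-Media Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dictionary-based emotion and prosociality scoring of
    short social-media posts, with weighted word frequencies and negation
    reversal; construction and validation of weighted lexicons from rater
    tables (candidate filtering, min-max normalization of mean ratings,
    inter-rater reliability); aggregation of per-post scores into a daily
    panel joined to an epidemic severity series; and moderated multiple
    regression on the standardized panel with bootstrap confidence intervals
    and simple-slopes analysis at pick-a-point moderator levels. A
    deterministic synthetic-data generator produces posts, lexicons and
    severity curves with known ground truth so the whole pipeline is
    testable without access to a crawled corpus.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
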