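Package: acasent
Title: Lexicon-Based Twitter Sentiment and Health Insurance Marketplace
    Enrollment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for infodemiology studies that
    link lexicon-scored Twitter sentiment about the Affordable Care Act (ACA)
    to state-level health-insurance-marketplace enrollment. Provides readers
    for archived tweet corpora (JSON-lines) and NRC-style sentiment lexicons,
    keyword and marketplace-handle collection filters, geolocation of tweets
    to US states from coordinates or free-text profile locations,
    frequency-weighted lexicon scoring of tweets with corpus Z-standardization
    and state aggregation, Welch group contrasts in standard-deviation units,
    rater-validation statistics (intraclass correlation, score-versus-human
    correlation), and a linear model of percent-eligible enrollment on state
    sentiment with heteroskedasticity-robust standard errors. A seeded
    synthetic-data module generates every input with planted ground truth so
    all stages can be verified without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    mgcv,
    sandwich,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
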