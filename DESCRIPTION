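Package: radtransfer
Title: Soil-Crop Transfer of Radiostrontium: Counting Data Reduction,
    Transfer Factors and an Exchange-Based Uptake Model
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Data reduction and radioecological analysis for gross-beta
    counting campaigns that determine Sr-90 activity concentrations in
    cultivated soil and crops.  Implements the activity-concentration
    estimator with Y-90 decay correction, counting-statistics uncertainty
    propagation, the Currie-type minimum detectable activity, organ-level
    soil-crop transfer factors with left-censoring rules, a steady-state
    soil-solution-plant exchange model with a pedotransfer estimate of
    cation exchange capacity, the field statistics layer (averages,
    Pearson screening, one-way ANOVA with Tukey HSD), and a synthetic
    campaign generator for estimator validation.  Ships the printed
    three-year two-field campaign tables as fixtures and reproduces the
    published transfer-factor and model-agreement tables from them.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
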