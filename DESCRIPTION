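Package: prevadjust
Title: Misclassification-Corrected Prevalence Estimation from Quota-Matched
    Survey Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the population prevalence of a disorder from
    an imperfect survey classifier. Simulates quota-matched web-panel cohorts
    with latent diagnostic classes and class-conditional survey features,
    provides a multilayer-perceptron case classifier and a rate-parameterised
    oracle classifier, corrects the crude positive count for expected false
    positives from confuser classes (healthy, major depressive disorder,
    bipolar disorder) and for expected false negatives via an externally
    validated true-positive to false-negative ratio, and attaches bootstrap
    confidence intervals. Ships the complete worked example in which a crude
    prevalence of 8.3% (62 positives of 750) adjusts to 1.6%.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
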