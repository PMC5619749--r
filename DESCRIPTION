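Package: fermopt
Title: Classification-Guided Prediction and Optimization of Fermentation Culture Conditions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for surrogate-assisted optimization of
    liquid-fermentation culture conditions, built around single-factor
    experiment series for flavonoid production by the medicinal fungus
    Phellinus. Records are split into high- and low-yield classes by a
    yield boundary, the minority class is rebalanced by SMOTE in
    gradient-unit space, logistic and feed-forward neural-network
    classifiers are evaluated with confusion-matrix reports, a
    Levenberg-Marquardt-trained multilayer network regresses yield on the
    high-yield conditions, and a real-coded elitist genetic algorithm
    searches the condition box for the predicted optimum. Includes the
    packaged experiment table, a synthetic single-factor data generator
    with a known optimum for end-to-end recovery testing, and tidy
    accessors with ggplot2 diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
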