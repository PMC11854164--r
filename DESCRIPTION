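Package: yieldsurf
Title: Response-Surface, Neural-Network and Genetic-Algorithm Optimization of Extraction Yields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for optimizing bioprocess extraction conditions from small
    designed experiments. Constructs three-factor Box-Behnken designs, fits
    the full second-order response-surface model in coded units with a
    lack-of-fit ANOVA and regression diagnostics, trains a small
    backpropagation neural surrogate (3-10-1) with early stopping, maximizes
    any fitted predictor with a real-coded elitist genetic algorithm, and
    compares models by R-squared, RMSE and average absolute deviation.
    Ships the published 17-run ultrasonic-assisted enzymatic extraction
    dataset for Cinnamomum cassia polysaccharide yield as a plain-text
    fixture, and a synthetic-surface generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
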