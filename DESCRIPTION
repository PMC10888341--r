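Package: blendsense
Title: Colour-Sensor Chemometrics for Vegetable-Oil Blends in Avocado Oil
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detection and quantification of vegetable-oil blends in avocado
    oil from low-cost RGBC colour-sensor readings. Provides a synthetic data
    generator emulating the blend designs used in colour-sensor authentication
    studies, clear-channel normalization of raw sensor counts, deterministic
    Kennard-Stone calibration/test partitioning, linear discriminant analysis,
    multiple linear regression and least-squares support vector machines
    (RBF kernel) implemented from first principles, and a full validation
    framework: precision, recall, accuracy, error rate, F1-score, Matthews
    correlation coefficient, RMSE, R-squared, Rm-squared, cRp-squared and
    y-randomization permutation testing, with report tables in the layout
    customary for food-authentication studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
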