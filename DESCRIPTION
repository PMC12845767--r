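Package: arsrisk
Title: Probabilistic Aggregate Exposure and Risk Assessment for Inorganic
    Arsenic
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Monte Carlo simulation of aggregate dietary and drinking-water
    exposure to inorganic arsenic (iAs) in communities affected by volcanic
    arsenic mobilisation. Reconstructs iAs concentrations in fish, clams and
    terrestrial crops from environmental measurements via bioaccumulation
    and soil-to-crop transfer factors, simulates a population with
    sex-specific anthropometry and food-intake variability, computes
    per-individual body-weight-normalised daily doses, characterises
    non-cancer (hazard quotient) and cancer (excess lifetime cancer risk)
    endpoints, and ranks exposure drivers by standardized regression
    coefficients and partial rank correlation coefficients.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
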