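Package: gordonschaefer
Title: Gordon-Schaefer Bioeconomic Analysis of Catch-Effort Fisheries
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Surplus-production bioeconomics for annual catch-effort fisheries
    data: logistic (Schaefer) biomass dynamics, dynamic-model parameter
    estimation with log-normal observation error and an initial-proportion
    input, equilibrium CPUE regression, closed-form biological and economic
    reference points (maximum sustainable yield, maximum economic yield,
    open-access equilibrium), discounted optimal sustainable yield across a
    discount-rate grid, and landing/effort tax levels that steer an open-access
    fishery to a target regime. Includes a synthetic catch-effort generator
    emulating four Omani fisheries so estimation is testable without the
    original ministry statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
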