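Package: vbpmed
Title: Value-Based Pricing of High-Technology Medical Devices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates value-based prices for high-technology medical
    devices from published cost-effectiveness parameters. Implements the
    standard cost-effectiveness algebra (incremental cost-effectiveness
    ratio, incremental cost, and the value-based price at a
    willingness-to-pay threshold), currency conversion through explicit
    exchange-rate tables, screening of device portfolios for usable
    cost-effectiveness data, and an end-to-end pipeline comparing
    value-based to real market prices under a primary and a secondary
    threshold. A synthetic two-arm discounted Markov cohort simulator
    generates realistic portfolios for validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
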