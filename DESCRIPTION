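Package: odormix
Title: Odor Interaction Analysis for Binary Odorant Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analyzes odor interaction (antagonism and synergism) in binary
    odorant mixtures. Converts chemical concentrations to odor-activity
    values and odor intensities through family-specific psychophysical laws,
    fits per-pair support vector regression intensity models with
    grid-searched radial-basis-function hyperparameters under k-fold
    cross-validation, densifies the composition space with model
    predictions, and quantifies interaction degree through odor-intensity
    reduction statistics on the lnOAV plane. Includes a seeded synthetic
    sensory-panel generator emulating olfactometry datasets so the whole
    pipeline is testable without measured panel data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
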