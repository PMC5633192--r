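Package: welanopt
Title: Surrogate-Assisted Optimization of Welan Gum Fermentation Conditions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models the relationship between nine culture-condition variables
    (glucose, yeast extract, KH2PO4, MgSO4, liquid volume, pH, temperature,
    rotational speed, inoculation amount) and Welan gum polysaccharide yield
    with an epsilon-support-vector regression surrogate using a Gaussian
    radial-basis kernel, selects the penalty and kernel parameters by
    grid-searched k-fold cross-validated mean squared error, and searches the
    bounded condition space for yield-maximizing media with a real-coded
    adaptive genetic algorithm whose crossover probability decays with
    generation and whose mutation probability adapts to each individual's
    fitness gap. Includes min-max normalization with yield-level stratified
    train/test splitting, a synthetic fermentation-surface generator for
    end-to-end testing, JSON model serialization, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    e1071,
    kernlab,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
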