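Package: swapmix
Title: Swap-Error Mixture Modelling for Sequential Visual Working Memory Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for continuous-report (delayed reproduction)
    working-memory experiments with sequentially presented items. Fits the
    three-component von Mises mixture model of recall errors (target, swap and
    uniform-guessing components) by multistart expectation-maximisation,
    computes shuffle-corrected non-target deviation histograms and heuristic
    swap measures, profiles swap errors by temporal and spatial distance
    between target and non-targets, converts t statistics to JZS default
    Bayes factors and simulates Bayesian sequential stopping rules. Includes a
    synthetic trial generator reproducing the structure of cued-recall
    experiments with four sequentially presented oriented or coloured items.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, tools, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
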