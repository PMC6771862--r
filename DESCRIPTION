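Package: psicatree
Title: Probabilistic Subgroup Identification Trees for Categorical Treatments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decision trees for subgroup identification in randomized trials
    with two or more treatment arms. Per-arm random-forest outcome models
    provide either bootstrap replicates or bias-corrected
    infinitesimal-jackknife prediction variances, from which the probability
    that each treatment is the best one is estimated for every participant by
    Monte Carlo. A tree is then grown on these probabilities using a
    misassignment-cost information gain with an optional chi-square
    pre-pruning gate, and each leaf reports aggregated best-treatment
    probabilities together with a label set of plausible best treatments.
    Includes generators for six benchmark trial models with known ground
    truth and accuracy, uncertainty, suspect and decision-accuracy metrics
    for simulation studies.
License: GPL-3
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
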