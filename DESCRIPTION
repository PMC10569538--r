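Package: interanimal
Title: Noise-Corrected Inter-Animal Consistency and Model Neural Predictivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates how well one animal's visual-cortical population
    activity predicts another's, after correcting for trial-to-trial noise,
    and scores candidate model representations against the same ceiling.
    Implements split-half bootstrap reliability with Spearman-Brown
    correction, identity / one-to-one / ridge / partial-least-squares
    population mappings, noise-corrected pairwise and pooled-source
    inter-animal consistency, noise-ceiling representational similarity
    analysis, unit-reliability and behavioral-modulation filters, temporal
    window selection for binned recordings, log-linear extrapolation of
    consistency over population size, shallow multi-stream convolutional
    architecture configurations with untrained feature extraction, the
    associated supervised and contrastive objective functions as desk-scale
    computations, a multi-animal cohort simulator with analytic ground truth,
    and a command-line interface chaining simulation, selection, and scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    mixOmics,
    e1071
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
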