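Package: timkit
Title: Target Inhibition Maps for Drug Sensitivity Prediction and Tumor
    Survival Circuit Inference
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts tumor-culture sensitivity to multi-target kinase
    inhibitors from functional drug-screen data (per-drug IC50 values plus
    per-drug-per-target EC50 values) and infers a minimal Boolean "tumor
    survival circuit" over a selected set of kinase targets.  Provides
    log-scale EC50-window binarization of drug target profiles, sequential
    floating forward search (SFFS) selection of a numerically relevant
    target set, monotone subset/superset interpolation of target-combination
    sensitivities (the Target Inhibition Map), extraction and block grouping
    of the minimal Boolean equation of effective target combinations,
    leave-one-out and repeated k-fold cross-validation harnesses, an
    EC50-based drug similarity measure, a synthetic Boolean-pathway
    benchmark generator, and a Boolean-network dynamics layer with
    inhibition transforms, attractor analysis and experiment-design
    counting bounds.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
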