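Package: bcidecode
Title: Nested Cross-Validation Hyperparameter Optimization for Imagined-Speech EEG Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying hyperparameter optimization in imagined-speech
    EEG decoding. Provides a seeded multi-subject synthetic EEG generator with
    1/f background, class-dependent band-power effects and eye-blink
    artefacts; preprocessing (zero-phase FIR band-pass, anti-aliased
    resampling, FastICA-based template screening of blink components);
    relative wavelet energy and filter-bank common spatial pattern features
    with mutual-information selection; six decoders (shallow, deep and
    EEGNet-style convolutional networks trained with ADAM, plus support
    vector machine, random forest and shrinkage-regularized LDA benchmarks);
    a nested k-fold cross-validation driver with exhaustive grid search and
    intra-/inter-subject hyperparameter selection modes; and a statistical
    comparison layer (repeated-measures and two-way ANOVA, Tukey HSD,
    precision scores, summary tables).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    e1071,
    randomForest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
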