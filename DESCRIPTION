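Package: modsense
Title: Simulated Psychophysics and Neurophysiology of Amplitude-Modulation
    Sensitivity in Sound-Recognition Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how sensitivity to amplitude modulation (AM)
    emerges in layered dilated-convolution networks optimized for natural
    sound recognition. Provides a synthetic corpus generator whose sound
    categories differ in their modulation statistics, envelope/fine-structure
    (chimera) degradations of training audio over single bands or an
    ERB-spaced filterbank, sinusoidal AM stimulus generation for six classic
    psychophysical conditions, simulated x-interval forced-choice AM-detection
    experiments with logistic-regression and template-correlation observers,
    asymmetric-sigmoid psychometric fitting with 70.7% thresholds, temporal
    modulation transfer function (TMTF) assembly and comparison against human
    reference TMTFs (pattern similarity, discrepancy, net difference), and
    simulated single-unit AM tuning (rate and synchrony coding) mapped onto
    auditory brain regions via one minus the Kolmogorov-Smirnov distance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
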