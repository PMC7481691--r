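Package: nbackiem
Title: Inverted Encoding Models for N-Back EEG Working-Memory Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis of continuous-performance N-back
    working-memory EEG experiments with oriented gratings. Provides
    constrained generators for 2-back, 1-back, delayed-recognition and
    functional-localizer task designs; a linear forward-model simulator of
    epoched multichannel EEG and 2-D gaze traces with a known
    priority-dependent representational state (perceptual, 90-degree
    remapped, or silent); epoching, baseline correction, median
    re-referencing, downsampling, epoch stitching and Hampel-filter gaze
    cleaning; an inverted encoding model (IEM) over six orientation-tuned
    channels with sliding-window training, leave-one-run-out
    cross-validation and reconstruction-fidelity scoring; group-level
    inference by one-sample t tests, Benjamini-Hochberg correction across
    analysis windows, and a sign-flip cluster-based permutation test; and a
    shrinkage-regularized Gaussian classifier for decoding orientation from
    gaze position.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
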