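Package: fewshotSED
Title: Few-Shot Bioacoustic Sound Event Detection with Transductive Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for few-shot sound event detection in long bioacoustic
    recordings. Implements Mel-spectrogram feature extraction with per-channel
    energy normalization (PCEN), SpecAugment-style spectrogram augmentation, a
    compact convolutional encoder with supervised and prototypical episodic
    pre-training, transductive information maximization (TIM) inference over
    support/query episodes, posterior-to-event segmentation with a shot-length
    post-filter, and event-based scoring via interval IoU with bipartite
    matching. A synthetic-scene generator renders annotated vocalization-like
    recordings (WAV plus DCASE-style CSV annotations) so the whole pipeline is
    testable end to end without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
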