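Package: entrain
Title: Event-Train Analysis for Pavlovian Conditioning Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for multi-region neural recordings acquired during
    combined Pavlovian reward and fear conditioning. Converts spike or calcium
    event trains to binned matrices and trial-aligned peri-event time histograms,
    scores freezing and port-visit behavior against the stimulus timeline,
    detects calcium events from dF/F traces, decodes stimulus identity from
    population activity (single-region, cross-stimulus transfer, three-class
    discrimination, and multi-region random-forest decoding with feature
    importance), estimates directed region-level transfer-entropy networks with
    surrogate-based significance, and computes spike-triggered averages and
    spike-field coherence. Ships a synthetic-session generator with planted,
    recoverable structure so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    nnet,
    ranger,
    signal,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
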