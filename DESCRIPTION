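Package: eegfuse
Title: Cross-Modal Attention Fusion of EEG and Video for Sequence
    Classification
Version: 0.1.0
Authors@R:
    person("Maintainer", "eegfuse", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A two-stream classifier for synchronized EEG and video
    sequences built from scaled dot-product attention primitives: a
    temporal-convolution EEG encoder with adaptive temporal attention, a
    video encoder with per-pixel spatial attention followed by temporal
    attention, and a cross-modal attention block that fuses the two
    context streams before a softmax prediction head.  Includes the full
    training strategy (Adam with decoupled weight decay, cosine cyclic
    learning rate with warm restarts, global gradient-norm clipping,
    early stopping), an ablation harness, macro-averaged classification
    metrics, seeded synthetic EEG/video generators with controllable
    unimodal and cross-modal class signal, EDF and dense-array readers
    and writers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
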