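Package: dclstm
Title: Double-Channel CNN-LSTM Text Classification with Hybrid Attention
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A from-scratch implementation of a double-channel neural text
    classifier for short labeled documents such as medical triage questions.
    Each channel (word-level and character-level) embeds the text and runs a
    multi-width convolutional branch and an LSTM branch with hybrid attention
    over hidden and cell states in parallel; the branch outputs are
    concatenated, fused across channels, and classified through a dense
    softmax head. Includes exact forward and backward passes in base R,
    Adam and Adadelta optimizers, one-vs-rest evaluation metrics and
    rank-based AUC, a synthetic corpus generator with plantable word-level
    and character-level class signal for ablation testing, word2vec text
    format embedding loading, CSV dataset readers, and a command-line
    interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
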