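# dclstm

Double-channel CNN–LSTM text classification with hybrid attention, in pure R.

## The problem

Routing short consultation texts — e.g. a patient's question to the right
outpatient department, or a tweet to a sentiment polarity — is a short-text
classification problem in which the decisive evidence may live at the **word**
level (which terms appear) or at the **character** level (morphology inside
words, crucial for Chinese medical terms and for out-of-vocabulary strings).
Single-granularity encoders can only see one of those signals.

`dclstm` implements a **double-channel** classifier. The same document is
embedded twice — as a word sequence and as a character sequence — and each
channel runs two branches **in parallel** on its embedded sequence `x`:

- a convolutional branch: 1-d convolutions with kernel widths 3/5/7
  (150 feature maps each by default), ReLU, and max-over-time pooling.
  Output length per width obeys `L' = ⌊(L + 2p − f)/s₀⌋ + 1`;
- a recurrent branch: an LSTM
  (`i, f, o = σ(W·[h_{t−1}, x_t] + b)`, `q = tanh(·)`,
  `c_t = f⊙c_{t−1} + i⊙q`, `h_t = o⊙tanh(c_t)`) followed by **hybrid
  attention**: each timestep's key is the concatenation `k_t = [h_t; c_t]`
  of hidden *and* cell state, scored by `e_t = v_aᵀ tanh(W_a k_t + b)`,
  softmax-normalized into weights `ω`, and the branch output is the context
  `Σ_t ω_t k_t`.

Each channel outputs `conv(x) ⊕ LSTM-attention(x)` (⊕ = concatenation); the
two channel outputs are concatenated, passed through a ReLU dense layer
(200 units, dropout 0.25) and a softmax head. Forward passes, full
backpropagation (including through the attention and both recurrences), and
Adam/Adadelta optimizers are implemented from scratch in base R and verified
against explicit-loop oracles and finite differences.

The package also ships the ablation/baseline suite sharing the same stack
(`cnn`, `lstm`, `gru`, `cnn_lstm` series variant, `word_only_dc`,
`char_only_dc`), evaluation metrics (one-vs-rest precision/recall/F1,
pooled accuracy, rank-based AUC), word2vec-text embedding loading, readers
for department/title/ask-style and polarity/tweet-style CSVs, and a
synthetic corpus generator that can plant word-level signal, char-level
signal, both split across classes, or none — so every architectural claim
is testable without external data.

## Worked example

```r
library(dclstm)

spec <- corpus_spec(n_classes = 3, n_per_class = 50, vocab_size = 150,
                    doc_length = c(5, 10), signal_mode = "word",
                    signal_strength = 0.9, seed = 11)
train <- generate_corpus(spec)
test  <- generate_corpus(corpus_spec(3, 30, 150, c(5, 10), "word", 0.9,
                                     seed = 1011, vocab_seed = 11))
df_train <- data.frame(label = train$label_names[train$labels + 1],
                       text = train$texts)
df_test  <- data.frame(label = test$label_names[test$labels + 1],
                       text = test$texts)
df_train$text[1]
#> "xxx hurohi foto role sara gunegi dofomo"   (label class_2; "xxx" is the marker)

cfg <- model_config(n_classes = 3, embed_dim = 16, d = 16, widths = c(2, 3),
                    n_maps = 8, dense_units = 32, dropout = 0.25,
                    t_word = 12, t_char = 48)
fit <- train_pipeline(df_train, kind = "dc_lstm", config = cfg,
                      tconfig = train_config(batch_size = 32, epochs = 10,
                                             seed = 11, learning_rate = 3e-3))
tail(fit$history, 2)
#>    epoch split       loss  accuracy
#> 9      9 train 0.10087095 0.9733333
#> 10    10 train 0.07528327 0.9733333

m <- evaluate_pipeline(fit$model, df_test)
metrics_report(m, "dc_lstm", "synthetic-test")
#>     model        dataset  accuracy precision    recall        f1
#> 1 dc_lstm synthetic-test 0.9444444 0.9465278 0.9444444 0.9447781
round(m$auc, 3)
#> [1] 0.992 0.989 0.991
```

Accuracy ~0.94 against a construction ceiling of ~0.93 ± sampling noise (10%
of documents carry no marker and are unclassifiable in principle); per-class
one-vs-rest AUCs ~0.99. Macro precision/recall/F1 are the unweighted class
means.

## Command line

```sh
Rscript inst/cli/dclstm.R generate --out ds --n_classes 3 --n_per_class 200 --signal_mode split
Rscript inst/cli/dclstm.R train    --data ds/train.csv --test_data ds/test.csv \
                                   --model dc_lstm --out run --epochs 8
Rscript inst/cli/dclstm.R evaluate --checkpoint run/checkpoint.rds --data ds/test.csv
Rscript inst/cli/dclstm.R predict  --checkpoint run/checkpoint.rds --text "zqzq foo bar"
```

Every run writes a JSON config snapshot beside its artifacts; flags override
config-file values; unknown keys fail with the key named.

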