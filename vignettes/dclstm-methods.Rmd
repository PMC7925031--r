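---
title: "dclstm: model, design decisions, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dclstm: model, design decisions, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

`dclstm` classifies short labeled texts with a double-channel architecture.
A document is tokenized twice — into words and into characters — and each
granularity gets its own vocabulary, embedding matrix, and encoder channel.
Within a channel the embedded sequence `x` feeds two branches *in parallel*:

1. **Convolutional branch.** 1-d convolutions of widths 3/5/7 (default),
   150 maps per width, each output cell the sum over the kernel window and
   all input channels plus a bias; output length follows
   `⌊(L + 2p − f)/s₀⌋ + 1`. Activations are rectified and max-over-time
   pooled, so each map contributes its single strongest response regardless
   of position.
2. **Recurrent branch.** A standard LSTM whose gates act on the
   concatenation `[h_{t−1}, x_t]` with one weight matrix per gate. Both the
   hidden sequence `h_t` and the cell sequence `c_t` are retained, because
   the attention layer consumes both: the *hybrid attention* key at time
   `t` is `k_t = [h_t; c_t]`, scored `e_t = v_aᵀ tanh(W_a k_t + b)`,
   normalized by a softmax into weights `ω` (non-negative, summing to 1),
   and the branch output is the context `Σ_t ω_t k_t` of dimension `2d`.

The channel output is the concatenation of the two branch vectors; the word
and char channel outputs are concatenated again, passed through dropout, a
ReLU dense layer, and a softmax head. All forward and backward passes are
hand-written base-R matrix code; there is no deep-learning framework
underneath. The training path is batched; a single-example path
(`channel_forward`, `dc_forward`) exists for inspection and is tested to
agree with the batched path to machine precision.

### Interpretive decisions the source left open

* **⊕ is concatenation.** Both the within-channel fusion and the
  cross-channel fusion use the same operator symbol; concatenation requires
  no dimension agreement between a conv branch of size `maps × widths` and
  an attention context of size `2d`, and matches the stated "mosaic" of
  results. Elementwise sum was rejected.
* **Attention weights the concatenated key.** The weighted sum could read
  over `h_t` alone or over `[h_t; c_t]`; since the key is *defined* as the
  concatenation and the sum reuses that symbol, we weight the
  concatenation. This makes the recurrent branch output `2d`-dimensional.
* **Pooling exponent conventions.** The pooling formula is a p-norm; its
  published limit statement uses a stray variable name (treated as a typo
  for `p → ∞`, giving max pooling), and at `p = 1` the formula literally
  yields a window *sum* — we implement the conventional arithmetic mean for
  the average mode and keep the raw p-norm for finite `p > 1` (inputs are
  post-ReLU, hence non-negative, which the p-norm requires). The test suite
  checks `p = 64` approximates the max within 1e-3.
* **Optimizer and loss contradictions.** The published hyperparameter table
  lists a learning-rate row naming Adadelta *and* an optimizer row naming
  Adam, and a binary cross-entropy loss for a 6-class softmax task. We
  default to Adam at 1e-3 with Adadelta selectable, and to categorical
  cross-entropy for more than two classes with binary cross-entropy (mean
  of per-class Bernoulli terms against the one-hot target) selectable.
* **Unstated sizes.** Sequence lengths (`t_word = 64`, `t_char = 128`),
  the attention dimension (`a = d`), and dropout placement (on the fused
  hidden vector, before the dense layer) are artifact defaults; each is a
  config value, not a claimed reproduction.

## Tunable parameters

| parameter | default | role |
|---|---|---|
| `embed_dim` | 300 | embedding dimension, both channels (published value) |
| `widths` | 3, 5, 7 | convolution kernel widths (published) |
| `n_maps` | 150 | feature maps per width (published) |
| `d` | 128 | LSTM hidden/cell dimension (published) |
| `a` | `d` | attention dimension (unstated; tied to `d`) |
| `dense_units` | 200 | dense layer width (published) |
| `dropout` | 0.25 | dropout on the fused vector, training only (published) |
| `batch_size` | 256 | mini-batch size (published) |
| `learning_rate` | 1e-3 | Adam step size (unstated; Adam's conventional default) |
| `t_word`, `t_char` | 64, 128 | fixed sequence lengths; head kept on truncation because the title/leading words carry the core demand in consultation-style data |
| `min_freq_word` | 2 | word-vocabulary frequency floor; prunes near-unique strings to the unknown token |

Reserved indices are global: padding = 0 (embedding row forced to zero and
excluded from updates), unknown = 1. Vocabulary order is frequency
descending with lexicographic tie-break (radix sort), making vocabularies
platform-independent.

## Numerical choices

* Softmax (head and attention) uses max-subtraction; mathematically
  identical, numerically stable.
* Probabilities are clamped at 1e-12 inside losses, with a warning, rather
  than erroring on a confident wrong prediction.
* Weights initialize Glorot-uniform; biases zero except the LSTM forget
  gate (+1, the standard trick to ease early gradient flow — the zero-bias
  textbook cell is available via `lstm_params(..., forget_bias = 0)` and is
  what the layer unit tests pin down).
* One integer seed drives initialization, shuffling, dropout, and the
  generator; derived sub-seeds stay below 2^31. Exact determinism is
  promised within one hardware/BLAS-thread configuration.
* Adam uses (0.9, 0.999, 1e-8); Adadelta uses (ρ = 0.95, 1e-6) and ignores
  the learning rate, as in its original unit-free formulation.
* The series `cnn_lstm` baseline aligns its three filter widths with
  `p = ⌊(f−1)/2⌋` same-style padding and truncates all width outputs to the
  shortest length before concatenating per-position features for the LSTM;
  the parallel architectures need no alignment.
* Gradient correctness is enforced by tests: analytic gradients of the
  attention layer and the LSTM step match central finite differences
  (step 1e-5) within relative 1e-4, and the full batched backward pass of
  every architecture was validated the same way during development.

## The synthetic world

The generator emulates short labeled consultation-style texts: 5–10
background tokens per document drawn uniformly from a 200-token vocabulary
of pronounceable CV-syllable strings, with a class marker inserted at a
uniformly random position with probability `signal_strength` (default 0.9).
Four signal modes:

* **word** — each class has a distinct marker token; the corpus is
  separable by a one-token rule, so a model that cannot reach ~`strength`
  accuracy has a defect.
* **char** — each class has a marker *character* embedded inside a freshly
  random carrier string per document. Carriers occur once, so the
  `min_freq = 2` word vocabulary prunes them to `<unk>`: the signal is
  invisible to the word channel by construction.
* **split** — first half of the classes carry word signal, second half char
  signal. The word-class markers are distinct *segmentations of one fixed
  character string* ("zqzq" vs "zq zq"): after whitespace removal the char
  channel sees identically distributed input for those classes and is
  provably at chance on them, while the word channel sees distinct
  vocabulary entries. Marker characters are disjoint from the background
  alphabet so no signal leaks through background tokens. Under
  `strength = 0.9` the construction ceilings are ≈ 0.93 for the full
  double channel and ≈ 0.70 for either single channel — the margin the
  ablation criterion tests.
* **none** — null control; best achievable accuracy is chance.

A train and a test corpus share one background vocabulary via `vocab_seed`
while differing in documents; without this, every test background token
would collapse to `<unk>` and the evaluation would measure
out-of-vocabulary behavior instead of the planted signal.

What the generator does **not** emulate: natural token frequency
distributions (background tokens are uniform, not Zipfian), topical or
syntactic structure, label noise, class imbalance, realistic Chinese
morphology, or documents longer than a few dozen tokens. A green ablation
therefore establishes that the two channels extract and fuse the signals
they are claimed to extract — not that the architecture attains any
particular accuracy on real clinical data. The published headline numbers
on the real corpora are out of reach at desk scale (external million-scale
datasets, pretrained embeddings, long training) and are not reproduced
here; loaders for both CSV dialects are provided so the pipeline can be
pointed at the real data where available.

## Known limitations

* Pure-R training is practical for the test-scale corpora (thousands of
  documents, dimensions in the tens) but orders of magnitude slower than a
  GPU framework at the published configuration (300-d embeddings, 150 maps,
  `d = 128`, batch 256).
* The LSTM/GRU are single-layer and unidirectional; no learning-rate
  schedules or early stopping beyond best-validation checkpointing.
* Word segmentation for unsegmented Chinese is a pluggable callback, not a
  bundled segmenter; tests use whitespace-delimited text.
* Embedding training (skip-gram/CBOW/GloVe) is out of scope: embeddings are
  loaded from word2vec text format or randomly initialized
  (uniform(−0.25, 0.25)), with a per-vocabulary coverage fraction reported.
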