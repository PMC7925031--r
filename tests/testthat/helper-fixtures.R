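# In-code fixtures shared by the tests.

tiny_vocabs <- function() {
  wv <- build_vocab(list(c("aa", "bb", "cc", "dd", "ee")), 1, 100, "word")
  cv <- build_vocab(list(letters[1:8]), 1, 100, "char")
  list(word = wv, char = cv)
}

tiny_config <- function(n_classes = 3L) {
  model_config(n_classes = n_classes, embed_dim = 4L, d = 3L,
               widths = c(2L, 3L), n_maps = 2L, dense_units = 5L,
               dropout = 0, t_word = 6L, t_char = 8L)
}

tiny_model <- function(kind = "dc_lstm", seed = 5L, n_classes = 3L) {
  v <- tiny_vocabs()
  init_model(kind, tiny_config(n_classes), v$word, v$char, seed = seed)
}

random_lstm_params <- function(d, e, seed) {
  set.seed(seed)
  p <- lstm_params(d, e, forget_bias = 0, init = "zero")
  for (nm in c("W_i", "W_f", "W_q", "W_o")) {
    p[[nm]] <- matrix(rnorm(d * (d + e), sd = 0.5), d, d + e)
  }
  for (nm in c("b_i", "b_f", "b_q", "b_o")) p[[nm]] <- rnorm(d, sd = 0.3)
  p
}

random_attn_params <- function(a, d, seed) {
  set.seed(seed)
  p <- attn_params(a, d, init = "zero")
  p$W_a <- matrix(rnorm(a * 2 * d, sd = 0.5), a, 2 * d)
  p$v_a <- rnorm(a, sd = 0.5)
  p$b <- rnorm(a, sd = 0.3)
  p
}

random_conv_params <- function(widths, n_maps, in_dim, seed,
                               stride = 1L, padding = 0L) {
  set.seed(seed)
  p <- conv_params(widths, n_maps, in_dim, stride, padding, init = "zero")
  for (key in names(p$kernels)) {
    p$kernels[[key]] <- matrix(rnorm(length(p$kernels[[key]]), sd = 0.5),
                               nrow(p$kernels[[key]]), n_maps)
    p$bias[[key]] <- rnorm(n_maps, sd = 0.3)
  }
  p
}

# small labeled data.frame from a synthetic corpus
corpus_df <- function(corpus) {
  data.frame(label = corpus$label_names[corpus$labels + 1L],
             text = corpus$texts, stringsAsFactors = FALSE)
}

# word2vec text fixture written to a temp file
write_w2v_fixture <- function(tokens, dim, header = TRUE, seed = 3L) {
  set.seed(seed)
  path <- tempfile(fileext = ".vec")
  lines <- character(0)
  if (header) lines <- sprintf("%d %d", length(tokens), dim)
  vecs <- list()
  for (tok in tokens) {
    v <- round(rnorm(dim), 4)
    vecs[[tok]] <- v
    lines <- c(lines, paste(tok, paste(v, collapse = " ")))
  }
  writeLines(lines, path)
  list(path = path, vectors = vecs)
}
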