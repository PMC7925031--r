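test_that("channel_forward composes branches with the documented shapes", {
  set.seed(8)
  e <- 4L; d <- 3L; Tn <- 7L
  E <- matrix(rnorm(Tn * e), Tn, e)
  cp <- random_conv_params(c(2L, 3L), 2L, e, 81)
  lp <- random_lstm_params(d, e, 82)
  ap <- random_attn_params(d, d, 83)
  out <- channel_forward(E, cp, pool_config(), lp, ap)
  expect_length(out$conv_part, 2 * 2)           # n_maps x |widths|
  expect_length(out$recurrent_part, 2 * d)      # attention context
  expect_identical(out$fused, c(out$conv_part, out$recurrent_part))
  # doubling n_maps doubles conv_part, leaves recurrent_part unchanged
  cp2 <- random_conv_params(c(2L, 3L), 4L, e, 81)
  out2 <- channel_forward(E, cp2, pool_config(), lp, ap)
  expect_length(out2$conv_part, 2 * length(out$conv_part))
  expect_equal(out2$recurrent_part, out$recurrent_part)
  # all-zero embeddings with zero parameters give a zero fused vector
  z <- channel_forward(matrix(0, Tn, e),
                       conv_params(c(2L, 3L), 2L, e, init = "zero"),
                       pool_config(),
                       lstm_params(d, e, forget_bias = 0, init = "zero"),
                       attn_params(d, d, init = "zero"))
  expect_equal(z$fused, rep(0, 4 + 2 * d))
  expect_error(channel_forward(matrix(0, 2, e), cp, pool_config(), lp, ap),
               "shorter")
})

test_that("dc_forward satisfies the softmax contract and is deterministic", {
  m <- tiny_model("dc_lstm")
  wid <- c(2L, 3L, 4L, 5L, 0L, 0L)
  cid <- c(2L, 3L, 4L, 5L, 6L, 7L, 0L, 0L)
  r1 <- dc_forward(m, wid, cid)
  expect_equal(sum(r1$probs), 1, tolerance = 1e-9)
  expect_true(all(r1$probs > 0))
  r2 <- dc_forward(m, wid, cid)
  expect_identical(r1$probs, r2$probs)
})

test_that("dc_forward matches the composed layer oracle", {
  for (seed in c(5, 6, 7)) {
    m <- tiny_model("dc_lstm", seed = seed)
    set.seed(seed)
    wid <- c(sample(2:6, 4, replace = TRUE), 0L, 0L)
    cid <- c(sample(2:9, 6, replace = TRUE), 0L, 0L)
    got <- dc_forward(m, wid, cid)$probs
    want <- oracle_dc_forward(m, wid, cid)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("batched forward agrees with the single-example path", {
  for (kind in c("dc_lstm", "word_only_dc", "char_only_dc")) {
    m <- tiny_model(kind, seed = 11)
    set.seed(11)
    B <- 5L
    wid <- matrix(sample(0:6, B * 6, replace = TRUE), B, 6)
    cid <- matrix(sample(0:9, B * 8, replace = TRUE), B, 8)
    fb <- dclstm:::model_forward_batch(m, wid, cid)
    for (b in seq_len(B)) {
      sb <- dc_forward(m,
                       if ("word" %in% m$structure$channels) wid[b, ],
                       if ("char" %in% m$structure$channels) cid[b, ])
      expect_equal(fb$probs[b, ], sb$probs, tolerance = 1e-12)
    }
  }
})

test_that("realized convolution lengths equal the closed form on a grid", {
  for (L in 3:12) {
    for (f in c(1L, 3L, 5L)) {
      for (pd in 0:2) {
        for (s0 in 1:2) {
          if (L + 2 * pd < f) next
          prm <- random_conv_params(f, 1L, 2L, L * 100 + f,
                                    stride = s0, padding = pd)
          out <- convolve(matrix(rnorm(L * 2), L, 2), prm)
          expect_identical(ncol(out[[as.character(f)]]),
                           conv_output_length(L, f, pd, s0))
        }
      }
    }
  }
})

test_that("baseline architectures have the promised structure", {
  cnn <- tiny_model("cnn")
  expect_false(any(grepl("lstm|gru|attn", names(cnn$params))))
  wo <- tiny_model("word_only_dc")
  expect_false(any(grepl("^char", names(wo$params))))
  expect_identical(wo$structure$channels, "word")
  gru <- tiny_model("gru")
  expect_true(any(grepl("gru", names(gru$params))))
  expect_false(any(grepl("lstm", names(gru$params))))
  series <- tiny_model("cnn_lstm")
  expect_true(series$structure$series)
  expect_error(build_baseline("transformer", tiny_config()), "unknown")
})

test_that("parameter counts match closed forms for a tiny config", {
  v <- tiny_vocabs()
  cfg <- tiny_config()
  e <- cfg$embed_dim; d <- cfg$d; mmap <- cfg$n_maps
  W <- length(cfg$widths); u <- cfg$dense_units; C <- cfg$n_classes
  Vw <- v$word$size; Vc <- v$char$size
  conv_n <- sum(cfg$widths * e * mmap + mmap)
  lstm_n <- 4 * (d * (d + e) + d)
  attn_n <- cfg$a * 2 * d + cfg$a + cfg$a
  head_n <- function(fdim) u * fdim + u + C * u + C
  # cnn: word embed + conv + head over m*W features
  expect_identical(n_params(build_baseline("cnn", cfg, v$word, v$char)),
                   as.integer(Vw * e + conv_n + head_n(mmap * W)))
  # lstm: word embed + lstm + head over d features
  expect_identical(n_params(build_baseline("lstm", cfg, v$word, v$char)),
                   as.integer(Vw * e + lstm_n + head_n(d)))
  # gru: 3 gates
  expect_identical(n_params(build_baseline("gru", cfg, v$word, v$char)),
                   as.integer(Vw * e + 3 * (d * (d + e) + d) + head_n(d)))
  # cnn_lstm: conv + lstm over m*W-dim inputs + head over d
  lstm_series_n <- 4 * (d * (d + mmap * W) + d)
  expect_identical(n_params(build_baseline("cnn_lstm", cfg, v$word, v$char)),
                   as.integer(Vw * e + conv_n + lstm_series_n + head_n(d)))
  # dc_lstm: both channels, conv + lstm + attention each, head over the
  # concatenation
  per_ch <- conv_n + lstm_n + attn_n
  fdim <- 2 * (mmap * W + 2 * d)
  expect_identical(n_params(build_baseline("dc_lstm", cfg, v$word, v$char)),
                   as.integer((Vw + Vc) * e + 2 * per_ch + head_n(fdim)))
})

test_that("checkpoints reload bit-exactly", {
  m <- tiny_model("dc_lstm", seed = 21)
  m$label_names <- c("a", "b", "c")
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(m2$params, m$params)
  expect_identical(m2$kind, m$kind)
  expect_identical(m2$label_names, m$label_names)
  expect_identical(m2$word_vocab$tokens, m$word_vocab$tokens)
  wid <- c(2L, 3L, 0L, 0L, 0L, 0L); cid <- c(2L, 3L, 4L, 0L, 0L, 0L, 0L, 0L)
  expect_identical(dc_forward(m, wid, cid)$probs,
                   dc_forward(m2, wid, cid)$probs)
  # a non-checkpoint file is rejected
  bogus <- tempfile()
  saveRDS(list(format = "other"), bogus)
  expect_error(load_checkpoint(bogus), "not a dclstm checkpoint")
})

test_that("embedding padding row is zero and stays zero through training", {
  co <- generate_corpus(corpus_spec(2, 10, 60, c(3, 5), "word", 1, 3))
  cfg <- model_config(2, embed_dim = 6, d = 4, widths = 2L, n_maps = 2,
                      dense_units = 8, dropout = 0, t_word = 8, t_char = 24)
  fit <- train_pipeline(corpus_df(co), "dc_lstm", cfg,
                        train_config(batch_size = 10, epochs = 2, seed = 3))
  expect_equal(fit$model$params$word_embed[1, ], rep(0, 6))
  expect_equal(fit$model$params$char_embed[1, ], rep(0, 6))
})
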