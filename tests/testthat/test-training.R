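test_that("loss_example evaluates both cross-entropies exactly", {
  expect_equal(loss_example(c(1, 0, 0), 0L, "categorical_ce"), 0,
               tolerance = 1e-9)
  expect_equal(loss_example(rep(0.25, 4), 2L, "categorical_ce"), log(4))
  expect_equal(loss_example(c(0.7, 0.3), 0L, "binary_ce"),
               -(log(0.7) + log(0.7)) / 2)
  expect_warning(loss_example(c(1, 0), 1L, "categorical_ce"), "clamped")
})

test_that("batch loss gradient on the logits matches finite differences", {
  set.seed(12)
  logits <- matrix(rnorm(6), 2, 3)
  labels <- c(0L, 2L)
  for (kind in c("categorical_ce", "binary_ce")) {
    lg <- dclstm:::batch_loss_grad(softmax(logits), labels, kind)
    h <- 1e-6
    for (i in seq_along(logits)) {
      up <- replace(logits, i, logits[i] + h)
      dn <- replace(logits, i, logits[i] - h)
      fd <- (dclstm:::batch_loss_grad(softmax(up), labels, kind)$loss -
             dclstm:::batch_loss_grad(softmax(dn), labels, kind)$loss) / (2 * h)
      expect_equal(lg$dlogits[i], fd, tolerance = 1e-5)
    }
  }
})

test_that("training with learning rate 0 leaves parameters unchanged", {
  co <- generate_corpus(corpus_spec(2, 8, 60, c(3, 5), "word", 1, 4))
  df <- corpus_df(co)
  cfg <- model_config(2, embed_dim = 5, d = 3, widths = 2L, n_maps = 2,
                      dense_units = 6, dropout = 0, t_word = 8, t_char = 24)
  prep <- fit_preprocessor(df, 8, 24, min_freq_word = 1)
  m <- init_model("dc_lstm", cfg, prep$word_vocab, prep$char_vocab, seed = 4)
  fit <- train_model(m, prep$encoded,
                     train_config(batch_size = 8, epochs = 1, seed = 4,
                                  learning_rate = 0))
  expect_equal(fit$final_model$params, m$params, tolerance = 1e-14)
})

test_that("training is deterministic under a fixed seed", {
  co <- generate_corpus(corpus_spec(2, 10, 60, c(3, 5), "word", 1, 6))
  df <- corpus_df(co)
  cfg <- model_config(2, embed_dim = 5, d = 3, widths = 2L, n_maps = 2,
                      dense_units = 6, dropout = 0.25, t_word = 8, t_char = 24)
  tc <- train_config(batch_size = 8, epochs = 2, seed = 17)
  f1 <- train_pipeline(df, "dc_lstm", cfg, tc)
  f2 <- train_pipeline(df, "dc_lstm", cfg, tc)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("loss trends downward on a separable toy corpus (adam default)", {
  co <- generate_corpus(corpus_spec(2, 15, 60, c(3, 5), "word", 1, 8))
  cfg <- model_config(2, embed_dim = 8, d = 6, widths = 2L, n_maps = 4,
                      dense_units = 8, dropout = 0, t_word = 8, t_char = 24)
  fit <- train_pipeline(corpus_df(co), "dc_lstm", cfg,
                        train_config(batch_size = 10, epochs = 6, seed = 8,
                                     learning_rate = 3e-3))
  h <- fit$history[fit$history$split == "train", ]
  expect_lt(h$loss[nrow(h)], h$loss[1])
})

test_that("adadelta also reduces loss on the toy corpus", {
  co <- generate_corpus(corpus_spec(2, 15, 60, c(3, 5), "word", 1, 9))
  cfg <- model_config(2, embed_dim = 8, d = 6, widths = 2L, n_maps = 4,
                      dense_units = 8, dropout = 0, t_word = 8, t_char = 24)
  fit <- train_pipeline(corpus_df(co), "dc_lstm", cfg,
                        train_config(batch_size = 10, epochs = 6, seed = 9,
                                     optimizer = "adadelta"))
  h <- fit$history[fit$history$split == "train", ]
  expect_lt(h$loss[nrow(h)], h$loss[1])
})

test_that("confusion produces one-vs-rest counts matching the tally oracle", {
  expect_equal(confusion(c(0L, 1L, 2L), c(0L, 1L, 2L), 3)$TP, c(1, 1, 1))
  cm <- confusion(c(0L, 0L), c(0L, 1L), 2)
  expect_equal(cm$TP, c(1, 0)); expect_equal(cm$FP, c(1, 0))
  expect_equal(cm$FN, c(0, 1)); expect_equal(cm$TN, c(0, 1))
  set.seed(20)
  for (rep in 1:5) {
    k <- sample(2:5, 1)
    pred <- sample(0:(k - 1), 100, replace = TRUE)
    act <- sample(0:(k - 1), 100, replace = TRUE)
    expect_equal(confusion(pred, act, k), oracle_confusion(pred, act, k))
    # TP+FP+TN+FN = n for every class
    cm <- confusion(pred, act, k)
    expect_true(all(cm$TP + cm$FP + cm$TN + cm$FN == 100))
  }
  expect_error(confusion(c(0L, 5L), c(0L, 1L), 2), "range")
})

test_that("compute_metrics reproduces the worked contingency and macro means", {
  m <- compute_metrics(data.frame(class = 0, TP = 8, FP = 2, TN = 88, FN = 2))
  expect_equal(m$per_class$precision, 0.8)
  expect_equal(m$per_class$recall, 0.8)
  expect_equal(m$per_class$f1, 0.8)
  expect_equal(m$per_class$accuracy, 0.96)
  # perfect predictions
  mp <- compute_metrics(confusion(0:2, 0:2, 3))
  expect_equal(mp$accuracy, 1); expect_equal(mp$macro_f1, 1)
  # hand-computed 3-class macro-F1 (n = 20 per class one-vs-rest)
  cts <- data.frame(class = 0:2,
                    TP = c(5, 3, 4), FP = c(1, 2, 3),
                    TN = c(12, 14, 10), FN = c(2, 1, 3))
  mm <- compute_metrics(cts)
  p <- c(5/6, 3/5, 4/7); r <- c(5/7, 3/4, 4/7)
  expect_equal(mm$macro_f1, mean(2 * p * r / (p + r)))
  # 0/0 ratios report 0 with a flag
  m0 <- compute_metrics(data.frame(class = 0, TP = 0, FP = 0, TN = 10, FN = 0))
  expect_equal(m0$per_class$precision, 0)
  expect_true(m0$undefined)
})

test_that("roc_auc equals the pairwise probability with midrank ties", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.3), c(1L, 0L, 1L, 0L), 1L), 0.75)
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1L, 1L, 0L, 0L), 1L), 1)
  expect_equal(roc_auc(rep(0.5, 6), rep(0:1, 3), 1L), 0.5)
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(5:50, 1)
    s <- round(runif(n), 2)              # rounded scores force ties
    lab <- sample(0:1, n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    expect_equal(roc_auc(s, lab, 1L), oracle_auc(s, lab, 1L))
  }
  expect_error(roc_auc(runif(4), rep(1L, 4), 1L), "undefined")
})

test_that("evaluate_predictions ties everything together", {
  set.seed(22)
  probs <- softmax(matrix(rnorm(60), 20, 3))
  labels <- sample(0:2, 20, replace = TRUE)
  m <- evaluate_predictions(probs, labels)
  preds <- max.col(probs) - 1L
  expect_equal(m$accuracy, mean(preds == labels))
  expect_length(m$auc, 3)
  rep <- metrics_report(m, "dc_lstm", "toy")
  expect_identical(names(rep),
                   c("model", "dataset", "accuracy", "precision", "recall", "f1"))
})
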