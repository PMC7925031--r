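## High-level pipeline: labeled data.frame in, trained model out. Shared by
## the CLI and the test/acceptance harnesses.

#' Fit preprocessing on labeled texts
#'
#' Builds word and char vocabularies and encodes the corpus at both
#' granularities. The word vocabulary defaults to `min_freq = 2` so that
#' near-unique carrier strings collapse to the unknown token (leaving
#' word-internal character signal visible only to the char channel).
#'
#' @param df data.frame with columns `label` (character or integer) and
#'   `text`.
#' @param t_word,t_char fixed sequence lengths.
#' @param min_freq_word,min_freq_char frequency floors for the vocabularies.
#' @param max_vocab_word,max_vocab_char vocabulary caps.
#' @param label_names optional fixed label ordering (required to encode a
#'   test split consistently with its training split).
#' @return list with `word_vocab`, `char_vocab`, `label_names`, `encoded`
#'   (word_ids, char_ids, labels), `t_word`, `t_char`.
#' @export
fit_preprocessor <- function(df, t_word = 64L, t_char = 128L,
                             min_freq_word = 2L, min_freq_char = 1L,
                             max_vocab_word = 50000L, max_vocab_char = 5000L,
                             label_names = NULL) {
  if (is.null(label_names)) label_names <- sort(unique(as.character(df$label)))
  labels <- match(as.character(df$label), label_names) - 1L
  if (anyNA(labels)) stop_dclstm("labels outside the fixed label set")
  word_tokens <- lapply(df$text, tokenize_words)
  char_tokens <- lapply(df$text, tokenize_chars)
  word_vocab <- build_vocab(word_tokens, min_freq_word, max_vocab_word, "word")
  char_vocab <- build_vocab(char_tokens, min_freq_char, max_vocab_char, "char")
  encoded <- encode_corpus(df$text, labels, word_vocab, char_vocab,
                           t_word, t_char)
  list(word_vocab = word_vocab, char_vocab = char_vocab,
       label_names = label_names, encoded = encoded,
       t_word = as.integer(t_word), t_char = as.integer(t_char))
}

#' Encode new texts with a fitted preprocessor (or trained model)
#'
#' @param texts character vector.
#' @param labels optional labels (character, matched to the fitted label
#'   set; or 0-based integers).
#' @param fitted a [fit_preprocessor()] result or a `dclstm_model`.
#' @param t_word,t_char sequence lengths (taken from `fitted` when present).
#' @return encoded list (word_ids, char_ids, labels).
#' @export
encode_with <- function(texts, labels = NULL, fitted,
                        t_word = NULL, t_char = NULL) {
  if (inherits(fitted, "dclstm_model")) {
    wv <- fitted$word_vocab; cv <- fitted$char_vocab
    tw <- fitted$config$t_word; tc <- fitted$config$t_char
    ln <- fitted$label_names
  } else {
    wv <- fitted$word_vocab; cv <- fitted$char_vocab
    tw <- fitted$t_word; tc <- fitted$t_char
    ln <- fitted$label_names
  }
  if (!is.null(t_word)) tw <- t_word
  if (!is.null(t_char)) tc <- t_char
  if (is.null(labels)) {
    labs <- rep(0L, length(texts))
  } else if (is.character(labels)) {
    labs <- match(labels, ln) - 1L
    if (anyNA(labs)) stop_dclstm("labels outside the model's label set")
  } else {
    labs <- as.integer(labels)
  }
  encode_corpus(texts, labs, wv, cv, tw, tc)
}

#' Train a classifier on a labeled data.frame
#'
#' End-to-end convenience: fits the preprocessor, initializes the requested
#' architecture, and trains it.
#'
#' @param df data.frame with `label` and `text` columns.
#' @param kind model kind (see [init_model()]).
#' @param config a [model_config()]; `n_classes` is overridden by the data.
#' @param tconfig a [train_config()].
#' @param val_df optional validation data.frame.
#' @param embeddings_word,embeddings_char optional word2vec text files.
#' @param min_freq_word frequency floor for the word vocabulary.
#' @return list with `model` (best checkpoint, carries vocabularies and
#'   label names), `history`, `prep`.
#' @export
train_pipeline <- function(df, kind = "dc_lstm",
                           config = model_config(n_classes = 2L),
                           tconfig = train_config(),
                           val_df = NULL,
                           embeddings_word = NULL, embeddings_char = NULL,
                           min_freq_word = 2L) {
  prep <- fit_preprocessor(df, t_word = config$t_word, t_char = config$t_char,
                           min_freq_word = min_freq_word)
  config$n_classes <- length(prep$label_names)
  we <- if (!is.null(embeddings_word)) {
    load_embeddings(embeddings_word, prep$word_vocab, config$embed_dim,
                    seed = tconfig$seed)
  }
  ce <- if (!is.null(embeddings_char)) {
    load_embeddings(embeddings_char, prep$char_vocab, config$embed_dim,
                    seed = tconfig$seed)
  }
  model <- init_model(kind, config, prep$word_vocab, prep$char_vocab,
                      we, ce, seed = tconfig$seed,
                      label_names = prep$label_names)
  val <- if (!is.null(val_df)) {
    encode_with(val_df$text, as.character(val_df$label), prep)
  }
  fit <- train_model(model, prep$encoded, tconfig, val_data = val)
  fit$model$label_names <- prep$label_names
  fit$final_model$label_names <- prep$label_names
  list(model = fit$model, final_model = fit$final_model,
       history = fit$history, prep = prep)
}

#' Evaluate a trained model on a labeled data.frame
#'
#' @param model a trained `dclstm_model`.
#' @param df data.frame with `label` and `text`.
#' @return [evaluate_predictions()] result.
#' @export
evaluate_pipeline <- function(model, df) {
  data <- encode_with(df$text, as.character(df$label), model)
  probs <- predict_proba(model, data)
  evaluate_predictions(probs, data$labels)
}

#' Read a labeled dataset in one of the supported CSV dialects
#'
#' @param path CSV file.
#' @param dialect `"cmedqa"` or `"sentiment140"`.
#' @return data.frame with `label` and `text`.
#' @export
read_dataset <- function(path, dialect = c("cmedqa", "sentiment140")) {
  dialect <- match.arg(dialect)
  if (dialect == "cmedqa") read_cmedqa(path) else read_sentiment140(path)
}
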