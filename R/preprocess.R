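## Preprocessing: tokenization, vocabularies, integer encoding, embeddings.
##
## Reserved indices are fixed globally: padding = 0, unknown = 1. Keeping them
## constant lets the padding embedding row be zeroed by index without any
## per-model configuration. All ids in this file are 0-based (as stored in
## encoded examples); R-side matrix row access adds 1.

PAD_INDEX <- 0L
UNK_INDEX <- 1L
PAD_TOKEN <- "<pad>"
UNK_TOKEN <- "<unk>"

#' Tokenize text into words
#'
#' Whitespace mode lowercases and splits on runs of whitespace; segmenter mode
#' delegates to a user-supplied segmentation callback (for unsegmented Chinese
#' text) and performs no case folding.
#'
#' @param text a character scalar.
#' @param mode `"whitespace"` or `"segmenter"`.
#' @param segmenter a function `character(1) -> character vector`; required
#'   when `mode = "segmenter"`.
#' @return character vector of tokens (length 0 for empty input).
#' @export
tokenize_words <- function(text, mode = c("whitespace", "segmenter"),
                           segmenter = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.character(text), length(text) == 1L)
  if (mode == "segmenter") {
    if (!is.function(segmenter)) {
      stop_dclstm("mode 'segmenter' requires a segmenter callback function")
    }
    toks <- segmenter(text)
    return(as.character(toks[nzchar(toks)]))
  }
  toks <- strsplit(tolower(text), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

#' Tokenize text into characters
#'
#' Splits into unicode code points with all whitespace removed. No case
#' folding: the character channel sees the surface form.
#'
#' @param text a character scalar.
#' @return character vector of single characters.
#' @export
tokenize_chars <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  ch <- strsplit(text, "")[[1]]
  ch[!grepl("[[:space:]]", ch)]
}

#' Build a vocabulary from tokenized documents
#'
#' Tokens are ranked by frequency (descending) with lexicographic order as the
#' tie-break — the tie-break is part of the contract so vocabularies are
#' reproducible across platforms. Indices are contiguous `0..|V|-1` with
#' padding at 0 and unknown at 1; those two slots count against `max_size`
#' and are never pruned.
#'
#' @param token_sequences list of character vectors (one per document).
#' @param min_freq minimum token frequency to keep (>= 1).
#' @param max_size maximum vocabulary size including the two reserved slots.
#' @param granularity `"word"` or `"char"` (metadata only).
#' @return an object of class `dclstm_vocab` with fields `granularity`,
#'   `tokens` (index order, reserved first), `token_to_index` (environment
#'   hash), `pad_index = 0`, `unk_index = 1`, `size`.
#' @export
build_vocab <- function(token_sequences, min_freq = 1L, max_size = 50000L,
                        granularity = c("word", "char")) {
  granularity <- match.arg(granularity)
  if (min_freq < 1L) stop_dclstm("min_freq must be >= 1")
  if (max_size < 2L) stop_dclstm("max_size must be >= 2 (reserved slots)")
  all_tokens <- unlist(token_sequences, use.names = FALSE)
  kept <- character(0)
  if (length(all_tokens)) {
    tab <- table(all_tokens)
    tab <- tab[tab >= min_freq]
    if (length(tab)) {
      # order by frequency desc, then token asc (byte order via the C locale
      # would differ; use plain order() which is deterministic per session --
      # force a radix sort for locale independence)
      toks <- names(tab)
      o <- order(-as.integer(tab), toks, method = "radix")
      kept <- toks[o]
    }
  }
  n_keep <- min(length(kept), max_size - 2L)
  kept <- kept[seq_len(n_keep)]
  tokens <- c(PAD_TOKEN, UNK_TOKEN, kept)
  t2i <- new.env(parent = emptyenv(), size = length(tokens))
  for (i in seq_along(tokens)) assign(tokens[i], i - 1L, envir = t2i)
  structure(list(
    granularity = granularity,
    tokens = tokens,
    token_to_index = t2i,
    pad_index = PAD_INDEX,
    unk_index = UNK_INDEX,
    size = length(tokens)
  ), class = "dclstm_vocab")
}

#' @export
print.dclstm_vocab <- function(x, ...) {
  cat(sprintf("<dclstm_vocab> granularity=%s size=%d (pad=0, unk=1)\n",
              x$granularity, x$size))
  invisible(x)
}

#' Look up token indices
#'
#' @param vocab a `dclstm_vocab`.
#' @param tokens character vector.
#' @return integer vector of 0-based indices; unknown tokens map to 1.
#' @export
vocab_lookup <- function(vocab, tokens) {
  if (!length(tokens)) return(integer(0))
  vapply(tokens, function(tok) {
    idx <- get0(tok, envir = vocab$token_to_index, inherits = FALSE)
    if (is.null(idx)) UNK_INDEX else idx
  }, integer(1), USE.NAMES = FALSE)
}

#' Encode a token sequence to a fixed-length id vector
#'
#' Unknown tokens map to the unknown index; sequences longer than `max_len`
#' keep their head (tail truncation); shorter ones are right-padded with the
#' padding index.
#'
#' @param tokens character vector.
#' @param vocab a `dclstm_vocab`.
#' @param max_len output length (>= 1).
#' @return integer vector of length `max_len` (0-based ids).
#' @export
encode <- function(tokens, vocab, max_len) {
  if (max_len < 1L) stop_dclstm("max_len must be >= 1")
  ids <- vocab_lookup(vocab, tokens)
  if (length(ids) > max_len) ids <- ids[seq_len(max_len)]
  c(ids, rep(PAD_INDEX, max_len - length(ids)))
}

#' Decode a 0-based id vector back to tokens
#'
#' @param ids integer vector of 0-based ids.
#' @param vocab a `dclstm_vocab`.
#' @param drop_pad drop padding positions (default TRUE).
#' @return character vector of tokens.
#' @export
decode <- function(ids, vocab, drop_pad = TRUE) {
  if (drop_pad) ids <- ids[ids != PAD_INDEX]
  vocab$tokens[ids + 1L]
}

#' Load (or randomly initialize) an embedding matrix for a vocabulary
#'
#' Reads word2vec text format: an optional `count dim` header line, then one
#' token followed by `dim` floats per line. In-vocabulary tokens found in the
#' file receive the file vectors; all other rows are sampled from
#' uniform(-0.25, 0.25) under `seed`. Row 1 (the padding index) is zeroed and
#' is excluded from gradient updates by the training code.
#'
#' @param path path to a word2vec text file, or `NULL` for pure random
#'   initialization.
#' @param vocab a `dclstm_vocab`.
#' @param dim embedding dimension (default 300, the published configuration).
#' @param seed integer seed for the random rows.
#' @param trainable should the matrix be updated during training?
#' @return list with `matrix` (|V| x dim), `trainable`, and `coverage` — the
#'   fraction of non-reserved vocabulary tokens covered by the file (0 when
#'   `path` is NULL).
#' @export
load_embeddings <- function(path = NULL, vocab, dim = 300L, seed = 1L,
                            trainable = TRUE) {
  set.seed(sub_seed(seed, 11L))
  mat <- matrix(stats::runif(vocab$size * dim, -0.25, 0.25), vocab$size, dim)
  covered <- 0L
  n_real <- vocab$size - 2L
  if (!is.null(path)) {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    if (length(lines)) {
      first <- strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]
      # header line: exactly two integer-looking fields
      if (length(first) == 2L && !anyNA(suppressWarnings(as.numeric(first)))) {
        lines <- lines[-1]
      }
      for (ln in lines) {
        if (!nzchar(trimws(ln))) next
        parts <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
        tok <- parts[1]
        vec <- suppressWarnings(as.numeric(parts[-1]))
        if (length(vec) != dim || anyNA(vec)) {
          stop_dclstm("embedding line for token '%s' has %d values, expected %d",
                      tok, length(vec), dim)
        }
        idx <- get0(tok, envir = vocab$token_to_index, inherits = FALSE)
        if (!is.null(idx) && idx > UNK_INDEX) {
          mat[idx + 1L, ] <- vec
          covered <- covered + 1L
        }
      }
    }
  }
  mat[PAD_INDEX + 1L, ] <- 0
  check_finite(mat, "embedding matrix")
  list(matrix = mat,
       trainable = isTRUE(trainable),
       coverage = if (n_real > 0L) covered / n_real else 0)
}

#' Encode a corpus at word and character granularity
#'
#' @param texts character vector of raw documents.
#' @param labels integer vector of 0-based class ids.
#' @param word_vocab,char_vocab vocabularies from [build_vocab()].
#' @param t_word,t_char fixed sequence lengths for the two channels.
#' @param mode,segmenter passed to [tokenize_words()].
#' @return list with `word_ids` (n x t_word integer matrix), `char_ids`
#'   (n x t_char), `labels`.
#' @export
encode_corpus <- function(texts, labels, word_vocab, char_vocab,
                          t_word = 64L, t_char = 128L,
                          mode = "whitespace", segmenter = NULL) {
  n <- length(texts)
  stopifnot(length(labels) == n)
  word_ids <- matrix(PAD_INDEX, n, t_word)
  char_ids <- matrix(PAD_INDEX, n, t_char)
  for (i in seq_len(n)) {
    word_ids[i, ] <- encode(tokenize_words(texts[i], mode, segmenter),
                            word_vocab, t_word)
    char_ids[i, ] <- encode(tokenize_chars(texts[i]), char_vocab, t_char)
  }
  list(word_ids = word_ids, char_ids = char_ids, labels = as.integer(labels))
}

#' Read a cMedQA-style CSV (columns department, title, ask)
#'
#' Text is `title + " " + ask`; the label is the department string.
#'
#' @param path CSV path (with header).
#' @return data.frame with columns `label` (character) and `text`.
#' @export
read_cmedqa <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("department", "title", "ask")
  if (!all(need %in% names(df))) {
    stop_dclstm("expected columns %s, got %s",
                paste(need, collapse = ","), paste(names(df), collapse = ","))
  }
  data.frame(label = as.character(df$department),
             text = paste(df$title, df$ask),
             stringsAsFactors = FALSE)
}

#' Read a Sentiment140-style headerless CSV (6 fields)
#'
#' Fields are polarity, id, date, query, user, text; the label is the polarity
#' and the text is field 6.
#'
#' @param path CSV path (no header).
#' @return data.frame with columns `label` (character) and `text`.
#' @export
read_sentiment140 <- function(path) {
  df <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                        encoding = "UTF-8")
  if (ncol(df) != 6L) {
    stop_dclstm("expected 6 fields per row, got %d", ncol(df))
  }
  data.frame(label = as.character(df[[1]]), text = as.character(df[[6]]),
             stringsAsFactors = FALSE)
}
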