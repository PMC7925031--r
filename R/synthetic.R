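## Synthetic corpus generator. Emulates short labeled consultation-style
## texts whose class is decodable from word-identity features, from
## word-internal character patterns, or only from both jointly — so each
## channel's contribution can be isolated without external data.
##
## Character inventory: background tokens are pronounceable CV syllables
## over consonants that never appear in any marker; marker characters come
## from a disjoint set, so character-level signal cannot leak through the
## background vocabulary.

BG_CONSONANTS <- c("b", "d", "f", "g", "h", "k", "l", "m", "n", "p", "r", "s", "t")
BG_VOWELS <- c("a", "e", "i", "o", "u")
MARKER_CHARS <- c("z", "q", "x", "j", "y", "c", "w", "v")

## pronounceable multi-character background token: 2-3 CV syllables
random_bg_token <- function() {
  n_syll <- sample(2:3, 1L)
  paste0(vapply(seq_len(n_syll), function(i) {
    paste0(sample(BG_CONSONANTS, 1L), sample(BG_VOWELS, 1L))
  }, character(1)), collapse = "")
}

#' Specification of a synthetic corpus
#'
#' @param n_classes number of classes (>= 2).
#' @param n_per_class documents per class.
#' @param vocab_size size of the background token vocabulary.
#' @param doc_length integer pair: min/max background tokens per document.
#' @param signal_mode `"word"` (a class-specific marker token),
#'   `"char"` (a class-specific marker character embedded inside otherwise
#'   novel carrier tokens, invisible at the word level), `"split"` (first
#'   half of the classes word-signal, second half char-signal; the word
#'   markers are distinct *segmentations* of one fixed character string, so
#'   after whitespace removal the character channel sees identically
#'   distributed input for every word class and is provably at chance on
#'   them), or `"none"` (null corpus, best achievable accuracy = chance).
#' @param signal_strength probability a document carries its class marker.
#' @param seed integer seed; identical specs generate identical corpora.
#' @param vocab_seed seed for the background token vocabulary (defaults to
#'   `seed`); give a train and a test corpus the same `vocab_seed` so they
#'   share one background vocabulary while differing in documents.
#' @return list of class `dclstm_corpus_spec`.
#' @export
corpus_spec <- function(n_classes = 4L, n_per_class = 500L, vocab_size = 200L,
                        doc_length = c(5L, 10L),
                        signal_mode = c("word", "char", "split", "none"),
                        signal_strength = 0.9, seed = 1L, vocab_seed = NULL) {
  signal_mode <- match.arg(signal_mode)
  if (n_classes < 2L) stop_dclstm("n_classes must be >= 2")
  if (signal_strength < 0 || signal_strength > 1) {
    stop_dclstm("signal_strength must be in [0, 1]")
  }
  if (vocab_size < 4L * n_classes) {
    stop_dclstm("vocab_size %d too small to host %d distinct class markers",
                vocab_size, n_classes)
  }
  if (signal_mode %in% c("word", "char") && n_classes > length(MARKER_CHARS)) {
    stop_dclstm("at most %d classes supported in mode '%s'",
                length(MARKER_CHARS), signal_mode)
  }
  if (signal_mode == "split" && n_classes > 6L) {
    stop_dclstm("at most 6 classes supported in split mode")
  }
  structure(list(n_classes = as.integer(n_classes),
                 n_per_class = as.integer(n_per_class),
                 vocab_size = as.integer(vocab_size),
                 doc_length = as.integer(doc_length),
                 signal_mode = signal_mode,
                 signal_strength = signal_strength,
                 seed = as.integer(seed),
                 vocab_seed = as.integer(if (is.null(vocab_seed)) seed else vocab_seed)),
            class = "dclstm_corpus_spec")
}

## markers for each class under a spec:
##   word-signal class -> $token (marker word); char-signal class -> $char
corpus_markers <- function(spec) {
  k <- spec$n_classes
  markers <- vector("list", k)
  if (spec$signal_mode == "word") {
    for (i in seq_len(k)) {
      markers[[i]] <- list(kind = "word",
                           token = strrep(MARKER_CHARS[i], 3L))
    }
  } else if (spec$signal_mode == "char") {
    for (i in seq_len(k)) markers[[i]] <- list(kind = "char", char = MARKER_CHARS[i])
  } else if (spec$signal_mode == "split") {
    n_word <- ceiling(k / 2)
    # word classes: distinct segmentations of ONE marker string ("zqzq",
    # "zq zq", "z qzq"). After whitespace removal every word class yields
    # the same character sequence, so the char channel is at chance on
    # them; the word channel sees distinct vocabulary entries.
    segmentations <- c("zqzq", "zq zq", "z qzq")
    for (i in seq_len(n_word)) {
      markers[[i]] <- list(kind = "word", token = segmentations[i])
    }
    # char classes: marker characters drawn from the far end of the pool
    for (i in (n_word + 1L):k) {
      markers[[i]] <- list(kind = "char",
                           char = MARKER_CHARS[length(MARKER_CHARS) - (i - n_word) + 1L])
    }
  } else {
    for (i in seq_len(k)) markers[[i]] <- list(kind = "none")
  }
  markers
}

## a carrier token: background-shaped string with the marker character
## inserted word-internally; fresh randomness per call makes carriers
## (near-)unique so frequency pruning drops them from the word vocabulary
make_carrier <- function(ch) {
  base <- paste0(random_bg_token(), random_bg_token())
  pos <- sample(2:(nchar(base)), 1L)
  paste0(substr(base, 1L, pos - 1L), ch, substr(base, pos, nchar(base)))
}

#' Generate a labeled synthetic corpus
#'
#' Background tokens are drawn uniformly from a seed-determined vocabulary
#' of pronounceable strings; class signal is injected per the spec's
#' `signal_mode` at a uniformly random position in each document (so neither
#' branch can exploit positional shortcuts).
#'
#' @param spec a [corpus_spec()].
#' @return list of class `dclstm_corpus` with `texts`, `labels` (0-based),
#'   `label_names`, `markers` (per-class marker info), `spec`.
#' @export
generate_corpus <- function(spec) {
  set.seed(sub_seed(spec$vocab_seed, 103L))
  bg_vocab <- character(0)
  while (length(bg_vocab) < spec$vocab_size) {
    bg_vocab <- unique(c(bg_vocab, replicate(spec$vocab_size, random_bg_token())))
  }
  bg_vocab <- sort(bg_vocab[seq_len(spec$vocab_size)])
  markers <- corpus_markers(spec)
  set.seed(sub_seed(spec$seed, 101L))
  n <- spec$n_classes * spec$n_per_class
  labels <- rep(seq_len(spec$n_classes) - 1L, each = spec$n_per_class)
  texts <- character(n)
  for (i in seq_len(n)) {
    len <- sample(spec$doc_length[1]:spec$doc_length[2], 1L)
    toks <- sample(bg_vocab, len, replace = TRUE)
    mk <- markers[[labels[i] + 1L]]
    if (mk$kind != "none" && stats::runif(1) < spec$signal_strength) {
      # a marker may be several tokens (a segmentation); insert the block
      # contiguously at a uniformly random position
      ins <- if (mk$kind == "word") strsplit(mk$token, " ", fixed = TRUE)[[1]]
             else make_carrier(mk$char)
      pos <- sample(seq_len(len + 1L), 1L)
      toks <- append(toks, ins, after = pos - 1L)
    }
    texts[i] <- paste(toks, collapse = " ")
  }
  ord <- sample.int(n)
  structure(list(texts = texts[ord], labels = labels[ord],
                 label_names = paste0("class_", seq_len(spec$n_classes) - 1L),
                 markers = markers, background_vocab = bg_vocab, spec = spec),
            class = "dclstm_corpus")
}

#' @export
print.dclstm_corpus <- function(x, ...) {
  cat(sprintf("<dclstm_corpus> %d docs, %d classes, mode=%s strength=%.2f\n",
              length(x$texts), x$spec$n_classes, x$spec$signal_mode,
              x$spec$signal_strength))
  invisible(x)
}

#' Rule-based classifiers over corpus markers
#'
#' `rule_classify` predicts by marker presence: the word rule looks for each
#' word-signal class's marker token, the char rule for each char-signal
#' class's marker character. Documents matching no marker (or several) fall
#' back to a seeded uniform random guess (`fallback = "random"`) or NA.
#' These are the independent probes used to verify that a split-signal
#' corpus is separable by exactly the intended channel.
#'
#' @param corpus a `dclstm_corpus`.
#' @param rule `"word"` or `"char"`.
#' @param fallback `"random"` or `"na"`.
#' @param seed seed for the random fallback.
#' @return integer vector of predicted 0-based labels (NA possible under
#'   `fallback = "na"`).
#' @export
rule_classify <- function(corpus, rule = c("word", "char"),
                          fallback = c("random", "na"), seed = 1L) {
  rule <- match.arg(rule)
  fallback <- match.arg(fallback)
  k <- corpus$spec$n_classes
  set.seed(sub_seed(seed, 131L))
  preds <- rep(NA_integer_, length(corpus$texts))
  for (i in seq_along(corpus$texts)) {
    hits <- integer(0)
    if (rule == "word") {
      toks <- tokenize_words(corpus$texts[i])
      for (cl in seq_len(k)) {
        mk <- corpus$markers[[cl]]
        if (mk$kind != "word") next
        pat <- strsplit(mk$token, " ", fixed = TRUE)[[1]]
        np <- length(pat)
        found <- FALSE
        if (length(toks) >= np) {
          for (s in seq_len(length(toks) - np + 1L)) {
            if (all(toks[s:(s + np - 1L)] == pat)) { found <- TRUE; break }
          }
        }
        if (found) hits <- c(hits, cl - 1L)
      }
    } else {
      chs <- tokenize_chars(corpus$texts[i])
      for (cl in seq_len(k)) {
        mk <- corpus$markers[[cl]]
        if (mk$kind == "char" && mk$char %in% chs) hits <- c(hits, cl - 1L)
      }
    }
    if (length(hits) == 1L) preds[i] <- hits
    else if (fallback == "random") preds[i] <- sample.int(k, 1L) - 1L
  }
  preds
}

#' Write a corpus to disk in a reader-compatible CSV dialect
#'
#' `cmedqa` emits a headered CSV with columns department, title, ask (the
#' first token becomes the title, the rest the ask, so `title + " " + ask`
#' reconstructs the document). `sentiment140` emits a headerless 6-field CSV
#' with the label in field 1 and the text in field 6.
#'
#' @param corpus a `dclstm_corpus`.
#' @param path output file path.
#' @param dialect `"cmedqa"` or `"sentiment140"`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(corpus, path, dialect = c("cmedqa", "sentiment140")) {
  dialect <- match.arg(dialect)
  if (!length(corpus$texts)) stop_dclstm("empty corpus")
  lab <- corpus$label_names[corpus$labels + 1L]
  if (dialect == "cmedqa") {
    first_space <- regexpr(" ", corpus$texts, fixed = TRUE)
    title <- ifelse(first_space > 0,
                    substr(corpus$texts, 1L, first_space - 1L), corpus$texts)
    ask <- ifelse(first_space > 0,
                  substr(corpus$texts, first_space + 1L, nchar(corpus$texts)), "")
    df <- data.frame(department = lab, title = title, ask = ask,
                     stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
  } else {
    df <- data.frame(polarity = corpus$labels, id = seq_along(corpus$texts),
                     date = "Mon Jan 01 00:00:00 UTC 2026", query = "NO_QUERY",
                     user = "synthetic", text = corpus$texts,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = ",", row.names = FALSE,
                       col.names = FALSE, qmethod = "double",
                       fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Indices of word-signal and char-signal classes
#'
#' @param corpus a `dclstm_corpus`.
#' @return list with `word` and `char` integer vectors of 0-based class ids.
#' @export
signal_classes <- function(corpus) {
  kinds <- vapply(corpus$markers, function(m) m$kind, character(1))
  list(word = which(kinds == "word") - 1L, char = which(kinds == "char") - 1L)
}
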