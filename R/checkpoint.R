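## Checkpointing. A checkpoint is a single archive holding every parameter
## tensor under its canonical name, the model configuration, and both
## vocabularies — sufficient for bit-exact reload.

vocab_to_list <- function(vocab) {
  if (is.null(vocab)) return(NULL)
  list(granularity = vocab$granularity, tokens = vocab$tokens)
}

vocab_from_list <- function(x) {
  if (is.null(x)) return(NULL)
  t2i <- new.env(parent = emptyenv(), size = length(x$tokens))
  for (i in seq_along(x$tokens)) assign(x$tokens[i], i - 1L, envir = t2i)
  structure(list(granularity = x$granularity, tokens = x$tokens,
                 token_to_index = t2i, pad_index = PAD_INDEX,
                 unk_index = UNK_INDEX, size = length(x$tokens)),
            class = "dclstm_vocab")
}

#' Save a model checkpoint
#'
#' @param model a `dclstm_model`.
#' @param path output path (conventionally `.rds`).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(format = "dclstm_checkpoint_v1",
               kind = model$kind, config = model$config,
               params = model$params,
               trainable_embeddings = model$trainable_embeddings,
               label_names = model$label_names,
               word_vocab = vocab_to_list(model$word_vocab),
               char_vocab = vocab_to_list(model$char_vocab)),
          path, version = 2L)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path path written by [save_checkpoint()].
#' @return a `dclstm_model` that reproduces the saved model bit-exactly.
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "dclstm_checkpoint_v1")) {
    stop_dclstm("'%s' is not a dclstm checkpoint", path)
  }
  structure(list(kind = x$kind, config = x$config,
                 structure = kind_structure(x$kind), params = x$params,
                 trainable_embeddings = x$trainable_embeddings,
                 label_names = x$label_names,
                 word_vocab = vocab_from_list(x$word_vocab),
                 char_vocab = vocab_from_list(x$char_vocab)),
            class = "dclstm_model")
}
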