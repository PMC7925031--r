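## Model assembly. A model object holds a flat named parameter list (the
## checkpoint layout), a config, and the two vocabularies. Seven
## architectures share this machinery:
##
##   dc_lstm       word + char channels, each conv || (LSTM + hybrid attention)
##   word_only_dc  word channel only, conv || (LSTM + attention)
##   char_only_dc  char channel only, conv || (LSTM + attention)
##   cnn           word channel, convolutional branch only
##   lstm          word channel, LSTM final hidden state (no attention)
##   gru           word channel, GRU final hidden state
##   cnn_lstm      word channel, series convolution -> LSTM final hidden

MODEL_KINDS <- c("dc_lstm", "cnn", "lstm", "cnn_lstm", "gru",
                 "word_only_dc", "char_only_dc")

#' Default model configuration
#'
#' Defaults follow the published configuration: filter widths 3/5/7 with 150
#' feature maps, ReLU activation, LSTM output 128, dense layer 200, dropout
#' 0.25, 300-d embeddings. Sequence lengths are artifact defaults (the
#' source configuration never states them).
#'
#' @param n_classes number of output classes.
#' @param embed_dim embedding dimension for both channels.
#' @param d LSTM/GRU hidden dimension.
#' @param a attention dimension (defaults to `d`).
#' @param widths convolution kernel widths.
#' @param n_maps feature maps per width.
#' @param dense_units dense layer width.
#' @param dropout dropout rate on the fused hidden vector (training only).
#' @param t_word,t_char fixed sequence lengths per channel.
#' @return named list of configuration values.
#' @export
model_config <- function(n_classes, embed_dim = 300L, d = 128L, a = NULL,
                         widths = c(3L, 5L, 7L), n_maps = 150L,
                         dense_units = 200L, dropout = 0.25,
                         t_word = 64L, t_char = 128L) {
  list(n_classes = as.integer(n_classes), embed_dim = as.integer(embed_dim),
       d = as.integer(d), a = as.integer(if (is.null(a)) d else a),
       widths = as.integer(widths), n_maps = as.integer(n_maps),
       dense_units = as.integer(dense_units), dropout = dropout,
       t_word = as.integer(t_word), t_char = as.integer(t_char))
}

kind_structure <- function(kind) {
  switch(kind,
    dc_lstm      = list(channels = c("word", "char"), conv = TRUE,
                        recurrent = TRUE, attention = TRUE, cell = "lstm",
                        series = FALSE),
    word_only_dc = list(channels = "word", conv = TRUE, recurrent = TRUE,
                        attention = TRUE, cell = "lstm", series = FALSE),
    char_only_dc = list(channels = "char", conv = TRUE, recurrent = TRUE,
                        attention = TRUE, cell = "lstm", series = FALSE),
    cnn          = list(channels = "word", conv = TRUE, recurrent = FALSE,
                        attention = FALSE, cell = "lstm", series = FALSE),
    lstm         = list(channels = "word", conv = FALSE, recurrent = TRUE,
                        attention = FALSE, cell = "lstm", series = FALSE),
    gru          = list(channels = "word", conv = FALSE, recurrent = TRUE,
                        attention = FALSE, cell = "gru", series = FALSE),
    cnn_lstm     = list(channels = "word", conv = TRUE, recurrent = TRUE,
                        attention = FALSE, cell = "lstm", series = TRUE),
    stop_dclstm("unknown model kind '%s' (expected one of %s)",
                kind, paste(MODEL_KINDS, collapse = ", "))
  )
}

## fused-vector width contributed by one channel
channel_out_dim <- function(st, cfg) {
  n <- 0L
  if (st$conv && !st$series) n <- n + cfg$n_maps * length(cfg$widths)
  if (st$recurrent) n <- n + if (st$attention) 2L * cfg$d else cfg$d
  n
}

#' Initialize a model
#'
#' @param kind one of `dc_lstm`, `cnn`, `lstm`, `cnn_lstm`, `gru`,
#'   `word_only_dc`, `char_only_dc`.
#' @param config a [model_config()].
#' @param word_vocab,char_vocab vocabularies (only those the architecture
#'   consumes are required).
#' @param word_embedding,char_embedding optional [load_embeddings()] results;
#'   random matrices are created when absent.
#' @param seed integer seed for parameter initialization.
#' @return object of class `dclstm_model` with `kind`, `config`, `structure`,
#'   `params` (flat named list), `word_vocab`, `char_vocab`.
#' @export
init_model <- function(kind, config, word_vocab = NULL, char_vocab = NULL,
                       word_embedding = NULL, char_embedding = NULL,
                       seed = 1L, label_names = NULL) {
  st <- kind_structure(kind)
  cfg <- config
  set.seed(sub_seed(seed, 23L))
  P <- list()
  trainable <- character(0)
  e <- cfg$embed_dim
  for (ch in st$channels) {
    vocab <- if (ch == "word") word_vocab else char_vocab
    if (is.null(vocab)) stop_dclstm("model kind '%s' needs a %s vocabulary", kind, ch)
    embres <- if (ch == "word") word_embedding else char_embedding
    if (is.null(embres)) {
      embres <- load_embeddings(NULL, vocab, dim = e, seed = sub_seed(seed, 31L))
    }
    P[[paste0(ch, "_embed")]] <- embres$matrix
    if (isTRUE(embres$trainable)) trainable <- c(trainable, paste0(ch, "_embed"))
    if (st$conv) {
      for (f in cfg$widths) {
        P[[sprintf("%s.conv.%d.kernel", ch, f)]] <- glorot(f * e, cfg$n_maps)
        P[[sprintf("%s.conv.%d.bias", ch, f)]] <- numeric(cfg$n_maps)
      }
    }
    if (st$recurrent) {
      rec_in <- if (st$series) cfg$n_maps * length(cfg$widths) else e
      if (st$cell == "lstm") {
        lp <- lstm_params(cfg$d, rec_in)
        for (nm in c("W_i", "W_f", "W_q", "W_o", "b_i", "b_f", "b_q", "b_o")) {
          P[[sprintf("%s.lstm.%s", ch, nm)]] <- lp[[nm]]
        }
      } else {
        gp <- gru_params(cfg$d, rec_in)
        for (nm in c("W_z", "W_r", "W_n", "b_z", "b_r", "b_n")) {
          P[[sprintf("%s.gru.%s", ch, nm)]] <- gp[[nm]]
        }
      }
      if (st$attention) {
        ap <- attn_params(cfg$a, cfg$d)
        P[[sprintf("%s.attn.W_a", ch)]] <- ap$W_a
        P[[sprintf("%s.attn.v_a", ch)]] <- ap$v_a
        P[[sprintf("%s.attn.b", ch)]] <- ap$b
      }
    }
  }
  fdim <- sum(vapply(st$channels, function(ch) channel_out_dim(st, cfg), integer(1)))
  P[["dense.W"]] <- glorot(cfg$dense_units, fdim)
  P[["dense.b"]] <- numeric(cfg$dense_units)
  P[["out.W"]] <- glorot(cfg$n_classes, cfg$dense_units)
  P[["out.b"]] <- numeric(cfg$n_classes)
  structure(list(kind = kind, config = cfg, structure = st, params = P,
                 trainable_embeddings = trainable,
                 word_vocab = word_vocab, char_vocab = char_vocab,
                 label_names = label_names),
            class = "dclstm_model")
}

#' @export
print.dclstm_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<dclstm_model> kind=%s classes=%d parameters=%d\n",
              x$kind, x$config$n_classes, np))
  invisible(x)
}

#' Build a baseline or ablation model
#'
#' Thin wrapper over [init_model()] restricted to the comparator suite; all
#' baselines share the preprocessing, head and training stack.
#'
#' @inheritParams init_model
#' @return a `dclstm_model`.
#' @export
build_baseline <- function(kind, config, word_vocab = NULL, char_vocab = NULL,
                           word_embedding = NULL, char_embedding = NULL,
                           seed = 1L) {
  if (!kind %in% MODEL_KINDS) {
    stop_dclstm("unknown baseline kind '%s'", kind)
  }
  init_model(kind, config, word_vocab, char_vocab,
             word_embedding, char_embedding, seed)
}

#' Count model parameters
#' @param model a `dclstm_model`.
#' @param include_embeddings count embedding matrices too?
#' @return integer total.
#' @export
n_params <- function(model, include_embeddings = TRUE) {
  nm <- names(model$params)
  if (!include_embeddings) nm <- nm[!grepl("_embed$", nm)]
  sum(vapply(model$params[nm], length, integer(1)))
}

## ---- parameter views (reference the flat list as classed layer params) ----

view_conv <- function(P, ch, cfg, padding = 0L) {
  kernels <- list(); bias <- list()
  for (f in cfg$widths) {
    kernels[[as.character(f)]] <- P[[sprintf("%s.conv.%d.kernel", ch, f)]]
    bias[[as.character(f)]] <- P[[sprintf("%s.conv.%d.bias", ch, f)]]
  }
  structure(list(widths = cfg$widths, n_maps = cfg$n_maps,
                 in_dim = cfg$embed_dim, stride = 1L, padding = padding,
                 kernels = kernels, bias = bias),
            class = "dclstm_conv_params")
}

view_lstm <- function(P, ch, cfg, rec_in) {
  structure(list(d = cfg$d, e = as.integer(rec_in),
                 W_i = P[[paste0(ch, ".lstm.W_i")]],
                 W_f = P[[paste0(ch, ".lstm.W_f")]],
                 W_q = P[[paste0(ch, ".lstm.W_q")]],
                 W_o = P[[paste0(ch, ".lstm.W_o")]],
                 b_i = P[[paste0(ch, ".lstm.b_i")]],
                 b_f = P[[paste0(ch, ".lstm.b_f")]],
                 b_q = P[[paste0(ch, ".lstm.b_q")]],
                 b_o = P[[paste0(ch, ".lstm.b_o")]]),
            class = "dclstm_lstm_params")
}

view_gru <- function(P, ch, cfg, rec_in) {
  structure(list(d = cfg$d, e = as.integer(rec_in),
                 W_z = P[[paste0(ch, ".gru.W_z")]],
                 W_r = P[[paste0(ch, ".gru.W_r")]],
                 W_n = P[[paste0(ch, ".gru.W_n")]],
                 b_z = P[[paste0(ch, ".gru.b_z")]],
                 b_r = P[[paste0(ch, ".gru.b_r")]],
                 b_n = P[[paste0(ch, ".gru.b_n")]]),
            class = "dclstm_gru_params")
}

view_attn <- function(P, ch, cfg) {
  structure(list(a = cfg$a, d = cfg$d,
                 W_a = P[[paste0(ch, ".attn.W_a")]],
                 v_a = P[[paste0(ch, ".attn.v_a")]],
                 b = P[[paste0(ch, ".attn.b")]]),
            class = "dclstm_attn_params")
}

## ---- series (cnn_lstm) convolution: keeps a per-position feature sequence --

series_conv_forward <- function(E, params) {
  B <- dim(E)[1]; Tn <- dim(E)[2]
  m <- params$n_maps
  lens <- integer(0); per_width <- list(); cache <- list()
  for (f in params$widths) {
    pf <- (f - 1L) %/% 2L
    To <- conv_output_length(Tn, f, pf, 1L)
    key <- as.character(f)
    U <- unfold_batch(E, f, padding = pf)
    Z <- sweep(U %*% params$kernels[[key]], 2L, params$bias[[key]], "+")
    A <- relu(Z)
    per_width[[key]] <- array(A, c(B, To, m))
    cache[[key]] <- list(Z = Z, To = To, pf = pf)
    lens <- c(lens, To)
  }
  Tmin <- min(lens)
  X <- array(0, c(B, Tmin, m * length(params$widths)))
  for (i in seq_along(params$widths)) {
    key <- as.character(params$widths[i])
    X[, , (i - 1L) * m + seq_len(m)] <- per_width[[key]][, seq_len(Tmin), , drop = FALSE]
  }
  list(X = X, Tmin = Tmin, cache = cache)
}

series_conv_backward <- function(dX, E, params, fwd) {
  B <- dim(E)[1]; Tn <- dim(E)[2]; e <- dim(E)[3]
  m <- params$n_maps
  dE <- array(0, c(B, Tn, e))
  grads <- list()
  for (i in seq_along(params$widths)) {
    f <- params$widths[i]; key <- as.character(f)
    cc <- fwd$cache[[key]]
    dA <- array(0, c(B, cc$To, m))
    dA[, seq_len(fwd$Tmin), ] <- dX[, , (i - 1L) * m + seq_len(m), drop = FALSE]
    dim(dA) <- c(B * cc$To, m)
    dZ <- dA * (cc$Z > 0)
    U <- unfold_batch(E, f, padding = cc$pf)
    grads[[paste0("conv.", key, ".kernel")]] <- t(U) %*% dZ
    grads[[paste0("conv.", key, ".bias")]] <- colSums(dZ)
    dU <- dZ %*% t(params$kernels[[key]])
    dE <- dE + fold_batch_grad(dU, B, Tn, e, f, padding = cc$pf)
  }
  list(grads = grads, dE = dE)
}

## ---- batched full forward / backward ----

model_forward_batch <- function(model, word_ids, char_ids, train = FALSE) {
  cfg <- model$config; st <- model$structure; P <- model$params
  B <- if ("word" %in% st$channels) nrow(word_ids) else nrow(char_ids)
  caches <- list(); fused <- list()
  for (ch in st$channels) {
    ids <- if (ch == "word") word_ids else char_ids
    E <- embed_batch(ids, P[[paste0(ch, "_embed")]])
    chc <- list(ids = ids, E = E)
    parts <- list()
    X <- E
    if (st$series) {
      sc <- series_conv_forward(E, view_conv(P, ch, cfg))
      chc$series <- sc
      X <- sc$X
    } else if (st$conv) {
      cb <- conv_branch_forward(E, view_conv(P, ch, cfg))
      chc$conv <- cb
      parts$conv <- cb$out
    }
    if (st$recurrent) {
      rec_in <- dim(X)[3]
      if (st$cell == "lstm") {
        fw <- lstm_batch_forward(X, view_lstm(P, ch, cfg, rec_in))
        chc$rec <- fw
        if (st$attention) {
          at <- attn_batch_forward(fw$H, fw$C, view_attn(P, ch, cfg))
          chc$attn <- at
          parts$rec <- at$context
        } else {
          parts$rec <- matrix(fw$H[, dim(X)[2], ], B, cfg$d)
        }
      } else {
        fw <- gru_batch_forward(X, view_gru(P, ch, cfg, rec_in))
        chc$rec <- fw
        parts$rec <- matrix(fw$H[, dim(X)[2], ], B, cfg$d)
      }
      chc$X <- X
    }
    fused[[ch]] <- do.call(cbind, parts)
    chc$part_dims <- vapply(parts, ncol, integer(1))
    caches[[ch]] <- chc
  }
  h <- do.call(cbind, fused)
  mask <- NULL
  hd <- h
  if (train && cfg$dropout > 0) {
    mask <- matrix(stats::runif(length(h)) >= cfg$dropout, nrow(h), ncol(h)) /
      (1 - cfg$dropout)
    hd <- h * mask
  }
  Zd <- sweep(hd %*% t(P[["dense.W"]]), 2L, P[["dense.b"]], "+")
  A1 <- relu(Zd)
  logits <- sweep(A1 %*% t(P[["out.W"]]), 2L, P[["out.b"]], "+")
  probs <- softmax(logits)
  list(probs = probs, logits = logits,
       cache = list(channels = caches, h = h, hd = hd, mask = mask,
                    Zd = Zd, A1 = A1))
}

model_backward_batch <- function(model, fwd, dlogits) {
  cfg <- model$config; st <- model$structure; P <- model$params
  cc <- fwd$cache
  G <- list()
  G[["out.W"]] <- t(dlogits) %*% cc$A1
  G[["out.b"]] <- colSums(dlogits)
  dA1 <- dlogits %*% P[["out.W"]]
  dZd <- dA1 * (cc$Zd > 0)
  G[["dense.W"]] <- t(dZd) %*% cc$hd
  G[["dense.b"]] <- colSums(dZd)
  dh <- dZd %*% P[["dense.W"]]
  if (!is.null(cc$mask)) dh <- dh * cc$mask
  col0 <- 0L
  for (ch in st$channels) {
    chc <- cc$channels[[ch]]
    nch <- sum(chc$part_dims)
    dfused <- dh[, col0 + seq_len(nch), drop = FALSE]
    col0 <- col0 + nch
    E <- chc$E
    dE <- array(0, dim(E))
    off <- 0L
    if (!is.null(chc$conv)) {
      nconv <- chc$part_dims[["conv"]]
      cb <- conv_branch_backward(dfused[, seq_len(nconv), drop = FALSE],
                                 E, view_conv(P, ch, cfg), chc$conv$cache)
      for (nm in names(cb$grads)) G[[paste0(ch, ".", nm)]] <- cb$grads[[nm]]
      dE <- dE + cb$dE
      off <- nconv
    }
    if (st$recurrent) {
      drec <- dfused[, off + seq_len(chc$part_dims[["rec"]]), drop = FALSE]
      X <- chc$X
      B <- dim(X)[1]; Tn <- dim(X)[2]; rec_in <- dim(X)[3]
      if (st$cell == "lstm") {
        lp <- view_lstm(P, ch, cfg, rec_in)
        if (st$attention) {
          ab <- attn_batch_backward(drec, chc$rec$H, chc$rec$C, chc$attn,
                                    view_attn(P, ch, cfg))
          G[[paste0(ch, ".attn.W_a")]] <- ab$grads$W_a
          G[[paste0(ch, ".attn.v_a")]] <- ab$grads$v_a
          G[[paste0(ch, ".attn.b")]] <- ab$grads$b
          dH <- ab$dH; dC <- ab$dC
        } else {
          dH <- array(0, c(B, Tn, cfg$d)); dC <- array(0, c(B, Tn, cfg$d))
          dH[, Tn, ] <- drec
        }
        lb <- lstm_batch_backward(dH, dC, X, chc$rec, lp)
        for (nm in names(lb$grads)) {
          G[[sprintf("%s.lstm.%s", ch, nm)]] <- lb$grads[[nm]]
        }
        dX <- lb$dX
      } else {
        gp <- view_gru(P, ch, cfg, rec_in)
        dH <- array(0, c(B, Tn, cfg$d))
        dH[, Tn, ] <- drec
        gb <- gru_batch_backward(dH, X, chc$rec, gp)
        for (nm in names(gb$grads)) {
          G[[sprintf("%s.gru.%s", ch, nm)]] <- gb$grads[[nm]]
        }
        dX <- gb$dX
      }
      if (st$series) {
        sb <- series_conv_backward(dX, E, view_conv(P, ch, cfg), chc$series)
        for (nm in names(sb$grads)) G[[paste0(ch, ".", nm)]] <- sb$grads[[nm]]
        dE <- dE + sb$dE
      } else {
        dE <- dE + dX
      }
    }
    embname <- paste0(ch, "_embed")
    if (embname %in% model$trainable_embeddings) {
      V <- nrow(P[[embname]]); e <- ncol(P[[embname]])
      dEflat <- dE
      dim(dEflat) <- c(dim(E)[1] * dim(E)[2], e)
      idx <- as.vector(chc$ids) + 1L
      rs <- rowsum(dEflat, idx)
      dEmb <- matrix(0, V, e)
      dEmb[as.integer(rownames(rs)), ] <- rs
      dEmb[PAD_INDEX + 1L, ] <- 0        # padding row never updates
      G[[embname]] <- dEmb
    }
  }
  G
}

## ---- public single-example forward ops ----

#' Forward pass of one channel (single example)
#'
#' Convolutional branch: [convolve()] with the configured widths, rectified,
#' then max-over-time pooled per feature map, concatenated across widths.
#' Recurrent branch: [lstm_sequence()] followed by [hybrid_attention()]; the
#' attention context (dimension `2d`) is the branch output. The channel
#' output is the concatenation of the two branch vectors.
#'
#' @param embedded `T x e` embedded sequence.
#' @param conv a `dclstm_conv_params`.
#' @param pool_cfg a `dclstm_pool_config` (default max-over-time).
#' @param lstm a `dclstm_lstm_params`.
#' @param attn a `dclstm_attn_params`.
#' @return list with `conv_part`, `recurrent_part`, `fused`.
#' @export
channel_forward <- function(embedded, conv, pool_cfg = pool_config(),
                            lstm, attn) {
  if (nrow(embedded) < max(conv$widths)) {
    stop_dclstm("sequence length %d shorter than widest kernel %d",
                nrow(embedded), max(conv$widths))
  }
  fmaps <- convolve(embedded, conv)
  conv_part <- unlist(lapply(fmaps, function(fm) {
    apply(relu(fm), 1L, function(row) pool(row, pool_cfg))
  }), use.names = FALSE)
  seq_out <- lstm_sequence(embedded, lstm)
  att <- hybrid_attention(seq_out$H, seq_out$C, attn)
  fused <- c(conv_part, att$context)
  list(conv_part = conv_part, recurrent_part = att$context, fused = fused,
       attention = att)
}

#' Full double-channel forward pass (single example)
#'
#' Embeds the word-id and char-id sequences with their respective matrices,
#' runs [channel_forward()] on each, concatenates the channel outputs into
#' the fused hidden vector, and applies the rectified dense layer and the
#' softmax output head. Dropout is not applied (inference semantics).
#'
#' @param model a `dclstm_model` of kind `dc_lstm`, `word_only_dc` or
#'   `char_only_dc`.
#' @param word_ids,char_ids 0-based id vectors (padded).
#' @return list with `hidden` (fused vector), `dense_activation`, `probs`
#'   (class probabilities summing to 1).
#' @export
dc_forward <- function(model, word_ids = NULL, char_ids = NULL) {
  cfg <- model$config; st <- model$structure; P <- model$params
  if (!(st$attention && st$conv && !st$series)) {
    stop_dclstm("dc_forward applies to the double-channel architectures")
  }
  parts <- list()
  for (ch in st$channels) {
    ids <- if (ch == "word") word_ids else char_ids
    if (is.null(ids)) stop_dclstm("model consumes the %s channel: ids required", ch)
    E <- P[[paste0(ch, "_embed")]][ids + 1L, , drop = FALSE]
    out <- channel_forward(E, view_conv(P, ch, cfg),
                           pool_config(),
                           view_lstm(P, ch, cfg, cfg$embed_dim),
                           view_attn(P, ch, cfg))
    parts[[ch]] <- out$fused
  }
  hidden <- unlist(parts, use.names = FALSE)
  a1 <- relu(as.numeric(P[["dense.W"]] %*% hidden) + P[["dense.b"]])
  logits <- as.numeric(P[["out.W"]] %*% a1) + P[["out.b"]]
  probs <- as.numeric(softmax(logits))
  list(hidden = hidden, dense_activation = a1, probs = probs)
}

#' Predict class probabilities for encoded data
#'
#' @param model a `dclstm_model`.
#' @param data list with `word_ids` and/or `char_ids` matrices (as produced
#'   by [encode_corpus()]).
#' @param batch_size mini-batch size for the forward passes.
#' @return `n x n_classes` matrix of probabilities.
#' @export
predict_proba <- function(model, data, batch_size = 256L) {
  st <- model$structure
  n <- if ("word" %in% st$channels) nrow(data$word_ids) else nrow(data$char_ids)
  out <- matrix(0, n, model$config$n_classes)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    w <- if (!is.null(data$word_ids)) data$word_ids[i:j, , drop = FALSE]
    ch <- if (!is.null(data$char_ids)) data$char_ids[i:j, , drop = FALSE]
    out[i:j, ] <- model_forward_batch(model, w, ch, train = FALSE)$probs
    i <- j + 1L
  }
  out
}

#' Predict class labels
#'
#' @inheritParams predict_proba
#' @return integer vector of 0-based predicted class ids.
#' @export
predict_labels <- function(model, data, batch_size = 256L) {
  max.col(predict_proba(model, data, batch_size), ties.method = "first") - 1L
}
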