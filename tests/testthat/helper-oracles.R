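# Explicit-loop reference implementations used as oracles. Deliberately
# written with scalar loops and no shared code with the package's
# vectorized/matrix paths.

oracle_conv <- function(input, params) {
  p <- params$padding; s0 <- params$stride; K <- ncol(input)
  x <- rbind(matrix(0, p, K), input, matrix(0, p, K))
  out <- list()
  for (f in params$widths) {
    key <- as.character(f)
    To <- floor((nrow(input) + 2 * p - f) / s0) + 1
    M <- matrix(0, params$n_maps, To)
    for (m in seq_len(params$n_maps)) {
      for (j in seq_len(To)) {
        acc <- params$bias[[key]][m]
        for (xx in seq_len(f)) {
          for (k in seq_len(K)) {
            acc <- acc + x[s0 * (j - 1) + xx, k] *
              params$kernels[[key]][(xx - 1) * K + k, m]
          }
        }
        M[m, j] <- acc
      }
    }
    out[[key]] <- M
  }
  out
}

oracle_pool <- function(x, window, stride, p) {
  if (is.null(window)) { window <- length(x); stride <- length(x) }
  n_out <- floor((length(x) - window) / stride) + 1
  out <- numeric(n_out)
  for (j in seq_len(n_out)) {
    win <- x[(stride * (j - 1) + 1):(stride * (j - 1) + window)]
    out[j] <- if (is.infinite(p)) max(win)
              else if (p == 1) sum(win) / length(win)
              else sum(win^p)^(1 / p)
  }
  out
}

oracle_lstm_step <- function(x, h_prev, c_prev, params) {
  d <- params$d
  z <- c(h_prev, x)
  gate <- function(W, b, act) {
    g <- numeric(d)
    for (r in seq_len(d)) {
      s <- b[r]
      for (cidx in seq_along(z)) s <- s + W[r, cidx] * z[cidx]
      g[r] <- act(s)
    }
    g
  }
  sig <- function(v) 1 / (1 + exp(-v))
  i <- gate(params$W_i, params$b_i, sig)
  f <- gate(params$W_f, params$b_f, sig)
  q <- gate(params$W_q, params$b_q, tanh)
  o <- gate(params$W_o, params$b_o, sig)
  cc <- numeric(d); h <- numeric(d)
  for (r in seq_len(d)) {
    cc[r] <- f[r] * c_prev[r] + i[r] * q[r]
    h[r] <- o[r] * tanh(cc[r])
  }
  list(h = h, c = cc)
}

oracle_lstm_sequence <- function(X, params) {
  d <- params$d
  h <- numeric(d); cc <- numeric(d)
  H <- matrix(0, nrow(X), d); C <- matrix(0, nrow(X), d)
  for (t in seq_len(nrow(X))) {
    st <- oracle_lstm_step(X[t, ], h, cc, params)
    h <- st$h; cc <- st$c
    H[t, ] <- h; C[t, ] <- cc
  }
  list(H = H, C = C)
}

oracle_attention <- function(H, C, params) {
  Tn <- nrow(H); d <- ncol(H); a <- params$a
  e <- numeric(Tn)
  for (t in seq_len(Tn)) {
    k <- c(H[t, ], C[t, ])
    s <- numeric(a)
    for (r in seq_len(a)) {
      acc <- params$b[r]
      for (cidx in seq_len(2 * d)) acc <- acc + params$W_a[r, cidx] * k[cidx]
      s[r] <- tanh(acc)
    }
    e[t] <- sum(params$v_a * s)
  }
  w <- exp(e - max(e)); w <- w / sum(w)
  ctx <- numeric(2 * d)
  for (t in seq_len(Tn)) ctx <- ctx + w[t] * c(H[t, ], C[t, ])
  list(weights = w, context = ctx, scores = e)
}

# composes the layer oracles into the full double-channel forward pass
oracle_dc_forward <- function(model, word_ids, char_ids) {
  P <- model$params; cfg <- model$config
  fused <- c()
  for (ch in model$structure$channels) {
    ids <- if (ch == "word") word_ids else char_ids
    E <- P[[paste0(ch, "_embed")]][ids + 1, , drop = FALSE]
    cp <- dclstm:::view_conv(P, ch, cfg)
    fmaps <- oracle_conv(E, cp)
    conv_part <- c()
    for (key in names(fmaps)) {
      M <- pmax(fmaps[[key]], 0)
      for (m in seq_len(nrow(M))) conv_part <- c(conv_part, max(M[m, ]))
    }
    lp <- dclstm:::view_lstm(P, ch, cfg, cfg$embed_dim)
    seq <- oracle_lstm_sequence(E, lp)
    at <- oracle_attention(seq$H, seq$C, dclstm:::view_attn(P, ch, cfg))
    fused <- c(fused, conv_part, at$context)
  }
  a1 <- pmax(as.numeric(P[["dense.W"]] %*% fused) + P[["dense.b"]], 0)
  logits <- as.numeric(P[["out.W"]] %*% a1) + P[["out.b"]]
  z <- exp(logits - max(logits))
  z / sum(z)
}

oracle_confusion <- function(pred, act, n_classes) {
  out <- NULL
  for (k in seq_len(n_classes) - 1) {
    tp <- 0; fp <- 0; tn <- 0; fn <- 0
    for (i in seq_along(act)) {
      if (act[i] == k && pred[i] == k) tp <- tp + 1
      if (act[i] != k && pred[i] == k) fp <- fp + 1
      if (act[i] != k && pred[i] != k) tn <- tn + 1
      if (act[i] == k && pred[i] != k) fn <- fn + 1
    }
    out <- rbind(out, data.frame(class = k, TP = tp, FP = fp, TN = tn, FN = fn))
  }
  out
}

oracle_auc <- function(scores, labels, class_id) {
  s_pos <- scores[labels == class_id]
  s_neg <- scores[labels != class_id]
  total <- 0
  for (sp in s_pos) {
    for (sn in s_neg) {
      total <- total + if (sp > sn) 1 else if (sp == sn) 0.5 else 0
    }
  }
  total / (length(s_pos) * length(s_neg))
}
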