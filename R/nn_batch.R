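## Batched forward/backward passes used by the training loop. The layer
## mathematics is identical to the single-example API in layers.R (the test
## suite asserts agreement); here everything is vectorized over the batch.
##
## Shapes: id matrices are B x T (0-based ids); embedded sequences are
## arrays (B, T, e); recurrent caches are arrays (B, T, d).

embed_batch <- function(ids, emb) {
  B <- nrow(ids); Tn <- ncol(ids); e <- ncol(emb)
  flat <- emb[as.vector(ids) + 1L, , drop = FALSE]   # (B*T) x e, b fastest
  array(flat, c(B, Tn, e))
}

## Unfold an embedded batch into convolution windows.
## Returns a (B*To) x (f*e) matrix; row (b, j) holds the window starting at
## position j of example b, columns ordered offset-major to match kernels.
unfold_batch <- function(E, f, stride = 1L, padding = 0L) {
  B <- dim(E)[1]; Tn <- dim(E)[2]; e <- dim(E)[3]
  if (padding > 0L) {
    Ep <- array(0, c(B, Tn + 2L * padding, e))
    Ep[, padding + seq_len(Tn), ] <- E
    E <- Ep
    Tn <- Tn + 2L * padding
  }
  To <- conv_output_length(Tn, f, 0L, stride)
  starts <- stride * (seq_len(To) - 1L) + 1L
  U <- matrix(0, B * To, f * e)
  for (x in seq_len(f)) {
    slab <- E[, starts + (x - 1L), , drop = FALSE]
    dim(slab) <- c(B * To, e)
    U[, (x - 1L) * e + seq_len(e)] <- slab
  }
  U
}

## Scatter the gradient on an unfolded window matrix back onto the embedded
## batch (reverse of unfold_batch).
fold_batch_grad <- function(dU, B, Tn, e, f, stride = 1L, padding = 0L) {
  Tp <- Tn + 2L * padding
  To <- conv_output_length(Tp, f, 0L, stride)
  starts <- stride * (seq_len(To) - 1L) + 1L
  dE <- array(0, c(B, Tp, e))
  for (x in seq_len(f)) {
    slab <- dU[, (x - 1L) * e + seq_len(e), drop = FALSE]
    dim(slab) <- c(B, To, e)
    dE[, starts + (x - 1L), ] <- dE[, starts + (x - 1L), , drop = FALSE] + slab
  }
  if (padding > 0L) dE <- dE[, padding + seq_len(Tn), , drop = FALSE]
  dE
}

## Conv branch: per width, convolve (stride 1, no padding), rectify, and
## max-over-time pool; outputs concatenated across widths -> B x (m*|widths|).
conv_branch_forward <- function(E, params) {
  B <- dim(E)[1]; Tn <- dim(E)[2]; e <- dim(E)[3]
  m <- params$n_maps
  parts <- list(); cache <- list()
  for (f in params$widths) {
    key <- as.character(f)
    To <- conv_output_length(Tn, f, 0L, 1L)
    U <- unfold_batch(E, f)
    Z <- U %*% params$kernels[[key]]
    Z <- sweep(Z, 2L, params$bias[[key]], "+")
    A <- relu(Z)
    Aarr <- array(A, c(B, To, m))
    pooled <- apply(Aarr, c(1L, 3L), max)          # B x m
    amax <- apply(Aarr, c(1L, 3L), which.max)      # B x m
    parts[[key]] <- pooled
    cache[[key]] <- list(U = U, Z = Z, amax = amax, To = To)
  }
  list(out = do.call(cbind, parts), cache = cache)
}

conv_branch_backward <- function(dout, E, params, cache) {
  B <- dim(E)[1]; Tn <- dim(E)[2]; e <- dim(E)[3]
  m <- params$n_maps
  dE <- array(0, c(B, Tn, e))
  grads <- list()
  col0 <- 0L
  for (f in params$widths) {
    key <- as.character(f)
    cc <- cache[[key]]
    To <- cc$To
    dpool <- dout[, col0 + seq_len(m), drop = FALSE]   # B x m
    col0 <- col0 + m
    # route gradient to the argmax position of each (example, map)
    dA <- matrix(0, B * To, m)
    for (k in seq_len(m)) {
      rows <- seq_len(B) + (cc$amax[, k] - 1L) * B
      dA[rows, k] <- dpool[, k]
    }
    dZ <- dA * (cc$Z > 0)
    grads[[paste0("conv.", key, ".kernel")]] <- t(cc$U) %*% dZ
    grads[[paste0("conv.", key, ".bias")]] <- colSums(dZ)
    dU <- dZ %*% t(params$kernels[[key]])
    dE <- dE + fold_batch_grad(dU, B, Tn, e, f)
  }
  list(grads = grads, dE = dE)
}

## Batched LSTM over an embedded batch X (B, T, e). Returns full hidden and
## cell sequences plus the gate caches needed for truncated-free BPTT.
lstm_batch_forward <- function(X, params) {
  B <- dim(X)[1]; Tn <- dim(X)[2]; e <- dim(X)[3]; d <- params$d
  tWi <- t(params$W_i); tWf <- t(params$W_f)
  tWq <- t(params$W_q); tWo <- t(params$W_o)
  H <- array(0, c(B, Tn, d)); C <- array(0, c(B, Tn, d))
  I <- array(0, c(B, Tn, d)); Fg <- array(0, c(B, Tn, d))
  Q <- array(0, c(B, Tn, d)); O <- array(0, c(B, Tn, d))
  TC <- array(0, c(B, Tn, d))
  h <- matrix(0, B, d); cst <- matrix(0, B, d)
  for (t in seq_len(Tn)) {
    Z <- cbind(h, matrix(X[, t, ], B, e))
    i <- sigmoid(sweep(Z %*% tWi, 2L, params$b_i, "+"))
    f <- sigmoid(sweep(Z %*% tWf, 2L, params$b_f, "+"))
    q <- tanh(sweep(Z %*% tWq, 2L, params$b_q, "+"))
    o <- sigmoid(sweep(Z %*% tWo, 2L, params$b_o, "+"))
    cst <- f * cst + i * q
    tc <- tanh(cst)
    h <- o * tc
    H[, t, ] <- h; C[, t, ] <- cst
    I[, t, ] <- i; Fg[, t, ] <- f; Q[, t, ] <- q; O[, t, ] <- o
    TC[, t, ] <- tc
  }
  list(H = H, C = C, cache = list(I = I, Fg = Fg, Q = Q, O = O, TC = TC))
}

## BPTT. dH, dC are (B, T, d) upstream gradients on every hidden/cell state
## (zero where unused). Returns parameter grads and dX (B, T, e).
lstm_batch_backward <- function(dH, dC, X, fwd, params) {
  B <- dim(X)[1]; Tn <- dim(X)[2]; e <- dim(X)[3]; d <- params$d
  cc <- fwd$cache
  dW_i <- matrix(0, d, d + e); dW_f <- matrix(0, d, d + e)
  dW_q <- matrix(0, d, d + e); dW_o <- matrix(0, d, d + e)
  db_i <- numeric(d); db_f <- numeric(d); db_q <- numeric(d); db_o <- numeric(d)
  dX <- array(0, c(B, Tn, e))
  dh_carry <- matrix(0, B, d); dc_carry <- matrix(0, B, d)
  for (t in rev(seq_len(Tn))) {
    i <- matrix(cc$I[, t, ], B, d); f <- matrix(cc$Fg[, t, ], B, d)
    q <- matrix(cc$Q[, t, ], B, d); o <- matrix(cc$O[, t, ], B, d)
    tc <- matrix(cc$TC[, t, ], B, d)
    c_prev <- if (t > 1L) matrix(fwd$C[, t - 1L, ], B, d) else matrix(0, B, d)
    h_prev <- if (t > 1L) matrix(fwd$H[, t - 1L, ], B, d) else matrix(0, B, d)
    dh <- matrix(dH[, t, ], B, d) + dh_carry
    dc <- matrix(dC[, t, ], B, d) + dc_carry + dh * o * (1 - tc^2)
    do_ <- dh * tc
    di <- dc * q; dq <- dc * i; df <- dc * c_prev
    dai <- di * i * (1 - i); daf <- df * f * (1 - f)
    dao <- do_ * o * (1 - o); daq <- dq * (1 - q^2)
    Z <- cbind(h_prev, matrix(X[, t, ], B, e))
    dW_i <- dW_i + t(dai) %*% Z; db_i <- db_i + colSums(dai)
    dW_f <- dW_f + t(daf) %*% Z; db_f <- db_f + colSums(daf)
    dW_q <- dW_q + t(daq) %*% Z; db_q <- db_q + colSums(daq)
    dW_o <- dW_o + t(dao) %*% Z; db_o <- db_o + colSums(dao)
    dZ <- dai %*% params$W_i + daf %*% params$W_f +
          daq %*% params$W_q + dao %*% params$W_o
    dh_carry <- dZ[, seq_len(d), drop = FALSE]
    dX[, t, ] <- dZ[, d + seq_len(e), drop = FALSE]
    dc_carry <- dc * f
  }
  list(grads = list(W_i = dW_i, W_f = dW_f, W_q = dW_q, W_o = dW_o,
                    b_i = db_i, b_f = db_f, b_q = db_q, b_o = db_o),
       dX = dX)
}

gru_batch_forward <- function(X, params) {
  B <- dim(X)[1]; Tn <- dim(X)[2]; e <- dim(X)[3]; d <- params$d
  tWz <- t(params$W_z); tWr <- t(params$W_r); tWn <- t(params$W_n)
  H <- array(0, c(B, Tn, d))
  Zg <- array(0, c(B, Tn, d)); Rg <- array(0, c(B, Tn, d))
  Ng <- array(0, c(B, Tn, d))
  h <- matrix(0, B, d)
  for (t in seq_len(Tn)) {
    x <- matrix(X[, t, ], B, e)
    Zin <- cbind(h, x)
    z <- sigmoid(sweep(Zin %*% tWz, 2L, params$b_z, "+"))
    r <- sigmoid(sweep(Zin %*% tWr, 2L, params$b_r, "+"))
    n <- tanh(sweep(cbind(r * h, x) %*% tWn, 2L, params$b_n, "+"))
    h <- (1 - z) * h + z * n
    H[, t, ] <- h; Zg[, t, ] <- z; Rg[, t, ] <- r; Ng[, t, ] <- n
  }
  list(H = H, cache = list(Zg = Zg, Rg = Rg, Ng = Ng))
}

gru_batch_backward <- function(dH, X, fwd, params) {
  B <- dim(X)[1]; Tn <- dim(X)[2]; e <- dim(X)[3]; d <- params$d
  cc <- fwd$cache
  dW_z <- matrix(0, d, d + e); dW_r <- matrix(0, d, d + e)
  dW_n <- matrix(0, d, d + e)
  db_z <- numeric(d); db_r <- numeric(d); db_n <- numeric(d)
  dX <- array(0, c(B, Tn, e))
  dh_carry <- matrix(0, B, d)
  for (t in rev(seq_len(Tn))) {
    z <- matrix(cc$Zg[, t, ], B, d); r <- matrix(cc$Rg[, t, ], B, d)
    n <- matrix(cc$Ng[, t, ], B, d)
    h_prev <- if (t > 1L) matrix(fwd$H[, t - 1L, ], B, d) else matrix(0, B, d)
    x <- matrix(X[, t, ], B, e)
    dh <- matrix(dH[, t, ], B, d) + dh_carry
    dz <- dh * (n - h_prev)
    dn <- dh * z
    dh_prev <- dh * (1 - z)
    dan <- dn * (1 - n^2)
    Zn <- cbind(r * h_prev, x)
    dW_n <- dW_n + t(dan) %*% Zn; db_n <- db_n + colSums(dan)
    dZn <- dan %*% params$W_n
    drh <- dZn[, seq_len(d), drop = FALSE]
    dr <- drh * h_prev
    dh_prev <- dh_prev + drh * r
    dx <- dZn[, d + seq_len(e), drop = FALSE]
    daz <- dz * z * (1 - z); dar <- dr * r * (1 - r)
    Zin <- cbind(h_prev, x)
    dW_z <- dW_z + t(daz) %*% Zin; db_z <- db_z + colSums(daz)
    dW_r <- dW_r + t(dar) %*% Zin; db_r <- db_r + colSums(dar)
    dZin <- daz %*% params$W_z + dar %*% params$W_r
    dh_carry <- dh_prev + dZin[, seq_len(d), drop = FALSE]
    dX[, t, ] <- dx + dZin[, d + seq_len(e), drop = FALSE]
  }
  list(grads = list(W_z = dW_z, W_r = dW_r, W_n = dW_n,
                    b_z = db_z, b_r = db_r, b_n = db_n),
       dX = dX)
}

attn_batch_forward <- function(H, C, params) {
  B <- dim(H)[1]; Tn <- dim(H)[2]; d <- dim(H)[3]; a <- params$a
  Earr <- matrix(0, B, Tn)
  Sarr <- array(0, c(B, Tn, a))
  tWa <- t(params$W_a)
  for (t in seq_len(Tn)) {
    K <- cbind(matrix(H[, t, ], B, d), matrix(C[, t, ], B, d))
    S <- tanh(sweep(K %*% tWa, 2L, params$b, "+"))
    Sarr[, t, ] <- S
    Earr[, t] <- S %*% params$v_a
  }
  W <- softmax(Earr)                    # B x T attention weights
  ctx <- matrix(0, B, 2L * d)
  for (t in seq_len(Tn)) {
    K <- cbind(matrix(H[, t, ], B, d), matrix(C[, t, ], B, d))
    ctx <- ctx + W[, t] * K
  }
  list(context = ctx, weights = W, cache = list(S = Sarr))
}

attn_batch_backward <- function(dctx, H, C, fwd, params) {
  B <- dim(H)[1]; Tn <- dim(H)[2]; d <- dim(H)[3]; a <- params$a
  W <- fwd$weights; Sarr <- fwd$cache$S
  dH <- array(0, c(B, Tn, d)); dC <- array(0, c(B, Tn, d))
  dW_e <- matrix(0, B, Tn)              # gradient on the weights
  Ks <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    K <- cbind(matrix(H[, t, ], B, d), matrix(C[, t, ], B, d))
    Ks[[t]] <- K
    dW_e[, t] <- rowSums(dctx * K)
    dKt <- W[, t] * dctx
    dH[, t, ] <- dKt[, seq_len(d), drop = FALSE]
    dC[, t, ] <- dKt[, d + seq_len(d), drop = FALSE]
  }
  de <- W * (dW_e - rowSums(dW_e * W))  # softmax Jacobian, rowwise
  dW_a <- matrix(0, a, 2L * d); dv_a <- numeric(a); db <- numeric(a)
  for (t in seq_len(Tn)) {
    S <- matrix(Sarr[, t, ], B, a)
    dS <- (de[, t] %o% params$v_a) * (1 - S^2)
    dW_a <- dW_a + t(dS) %*% Ks[[t]]
    db <- db + colSums(dS)
    dv_a <- dv_a + as.numeric(t(S) %*% de[, t])
    dK2 <- dS %*% params$W_a
    dH[, t, ] <- dH[, t, ] + dK2[, seq_len(d), drop = FALSE]
    dC[, t, ] <- dC[, t, ] + dK2[, d + seq_len(d), drop = FALSE]
  }
  list(grads = list(W_a = dW_a, v_a = dv_a, b = db), dH = dH, dC = dC)
}
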