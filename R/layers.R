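## Core layers, single-example API. Each operation is a direct matrix
## transcription of its defining formula; the batched training path in
## nn_batch.R is checked against these in the test suite, and these in turn
## are checked against explicit-loop oracles.

#' Convolution output length
#'
#' Closed form for the length of a 1-d convolution over a length-`L` input
#' with kernel width `f`, zero padding `p` on each side, and stride `s0`:
#' `floor((L + 2p - f)/s0) + 1`.
#'
#' @param L input length (>= 1).
#' @param f kernel width (>= 1).
#' @param p zero-padding per side (>= 0).
#' @param s0 stride (>= 1).
#' @return integer output length.
#' @export
conv_output_length <- function(L, f, p = 0L, s0 = 1L) {
  if (L < 1L || f < 1L || s0 < 1L || p < 0L) {
    stop_dclstm("invalid geometry: L=%d f=%d p=%d s0=%d", L, f, p, s0)
  }
  if (L + 2L * p < f) {
    stop_dclstm("invalid geometry: L + 2p = %d < f = %d", L + 2L * p, f)
  }
  as.integer(floor((L + 2L * p - f) / s0) + 1L)
}

#' Construct convolution parameters
#'
#' One kernel bank per width. Kernels are stored as `(f * in_dim) x n_maps`
#' matrices whose rows are ordered offset-major: row `(x-1)*in_dim + k` is
#' kernel position `x`, input channel `k`.
#'
#' @param widths integer vector of kernel widths (default `c(3, 5, 7)`).
#' @param n_maps feature maps per width (default 150).
#' @param in_dim input channel count (embedding dimension).
#' @param stride convolution stride.
#' @param padding zero padding per side.
#' @param init `"glorot"` or `"zero"`.
#' @return list of class `dclstm_conv_params`.
#' @export
conv_params <- function(widths = c(3L, 5L, 7L), n_maps = 150L, in_dim,
                        stride = 1L, padding = 0L, init = "glorot") {
  kernels <- list()
  bias <- list()
  for (f in widths) {
    kernels[[as.character(f)]] <-
      if (init == "zero") matrix(0, f * in_dim, n_maps)
      else glorot(f * in_dim, n_maps)
    bias[[as.character(f)]] <- numeric(n_maps)
  }
  structure(list(widths = as.integer(widths), n_maps = as.integer(n_maps),
                 in_dim = as.integer(in_dim), stride = as.integer(stride),
                 padding = as.integer(padding),
                 kernels = kernels, bias = bias),
            class = "dclstm_conv_params")
}

## zero-pad an L x K matrix with p rows of zeros on each side
pad_input <- function(input, p) {
  if (p == 0L) return(input)
  K <- ncol(input)
  rbind(matrix(0, p, K), input, matrix(0, p, K))
}

#' 1-d convolution over an embedded sequence
#'
#' Each output cell is the sum over the kernel window and all input channels
#' of input times kernel weight, plus a per-map bias. Zero padding of
#' `params$padding` positions is applied on each side.
#'
#' @param input `L x K` numeric matrix (sequence positions x channels).
#' @param params a `dclstm_conv_params`.
#' @return named list (one element per width) of `n_maps x out_length`
#'   feature-map matrices.
#' @export
convolve <- function(input, params) {
  if (ncol(input) != params$in_dim) {
    stop_dclstm("input has %d channels, params expect %d",
                ncol(input), params$in_dim)
  }
  x <- pad_input(input, params$padding)
  L <- nrow(input)
  out <- list()
  for (f in params$widths) {
    key <- as.character(f)
    To <- conv_output_length(L, f, params$padding, params$stride)
    # unfold: row j holds the window starting at stride*(j-1)+1, flattened
    # offset-major to match the kernel layout
    U <- matrix(0, To, f * params$in_dim)
    for (j in seq_len(To)) {
      s <- params$stride * (j - 1L)
      U[j, ] <- as.numeric(t(x[(s + 1L):(s + f), , drop = FALSE]))
    }
    Z <- U %*% params$kernels[[key]]            # To x n_maps
    Z <- sweep(Z, 2L, params$bias[[key]], "+")
    out[[key]] <- t(Z)                          # n_maps x To
  }
  out
}

#' Pooling configuration
#'
#' @param window pooling window; `NULL` selects max-over-time (one window
#'   spanning the whole row).
#' @param stride pooling stride (defaults to `window`).
#' @param exponent pooling exponent `p`: `1` selects average pooling
#'   (arithmetic mean), `Inf` plain maximum, finite `p > 1` the p-norm
#'   `(sum A^p)^(1/p)` (inputs must be non-negative, e.g. post-rectifier).
#' @return list of class `dclstm_pool_config`.
#' @export
pool_config <- function(window = NULL, stride = NULL, exponent = Inf) {
  if (!is.infinite(exponent) && exponent < 1) {
    stop_dclstm("pooling exponent must be >= 1 or Inf")
  }
  structure(list(window = window,
                 stride = if (is.null(stride)) window else as.integer(stride),
                 exponent = exponent),
            class = "dclstm_pool_config")
}

#' Pool one feature-map row
#'
#' @param x numeric vector (one feature map).
#' @param config a `dclstm_pool_config`.
#' @return pooled numeric vector (length 1 for max-over-time).
#' @export
pool <- function(x, config) {
  w <- config$window
  if (is.null(w)) {       # max-over-time: one window over the whole row
    w <- length(x)
    stride <- w
  } else {
    stride <- config$stride
  }
  if (w > length(x)) stop_dclstm("pool window %d > input length %d", w, length(x))
  n_out <- floor((length(x) - w) / stride) + 1L
  p <- config$exponent
  vapply(seq_len(n_out), function(j) {
    win <- x[(stride * (j - 1L) + 1L):(stride * (j - 1L) + w)]
    if (is.infinite(p)) max(win)
    else if (p == 1) mean(win)
    else {
      if (any(win < 0)) stop_dclstm("finite-exponent pooling requires non-negative inputs")
      sum(win^p)^(1 / p)
    }
  }, numeric(1))
}

#' Construct LSTM parameters
#'
#' One weight matrix per gate, each of shape `d x (d + e)`, applied to the
#' concatenation `[h_prev, x_t]`, plus a length-`d` bias per gate. The gates
#' are input (`i`), forget (`f`), candidate (`q`, tanh) and output (`o`).
#'
#' @param d hidden/memory dimension (default 128).
#' @param e input dimension.
#' @param forget_bias initial forget-gate bias (a small positive value eases
#'   early gradient flow; 0 gives the textbook cell).
#' @param init `"glorot"` or `"zero"`.
#' @return list of class `dclstm_lstm_params`.
#' @export
lstm_params <- function(d = 128L, e, forget_bias = 1, init = "glorot") {
  mk <- function() if (init == "zero") matrix(0, d, d + e) else glorot(d, d + e)
  structure(list(d = as.integer(d), e = as.integer(e),
                 W_i = mk(), W_f = mk(), W_q = mk(), W_o = mk(),
                 b_i = numeric(d), b_f = rep(forget_bias, d),
                 b_q = numeric(d), b_o = numeric(d)),
            class = "dclstm_lstm_params")
}

#' One LSTM time step
#'
#' Gates: `i = sigmoid(W_i [h,x] + b_i)`, `f = sigmoid(W_f [h,x] + b_f)`,
#' `q = tanh(W_q [h,x] + b_q)`, `o = sigmoid(W_o [h,x] + b_o)`;
#' state: `c_t = f * c_prev + i * q`, `h_t = o * tanh(c_t)`.
#'
#' @param x input vector of length `e`.
#' @param state list with `h` and `c` (length `d` each).
#' @param params a `dclstm_lstm_params`.
#' @return list with `h`, `c` and a `gates` cache (`i`, `f`, `q`, `o`,
#'   `tanh_c`) used by the analytic backward pass.
#' @export
lstm_step <- function(x, state, params) {
  check_finite(x, "lstm input")
  z <- c(state$h, x)
  i <- sigmoid(as.numeric(params$W_i %*% z) + params$b_i)
  f <- sigmoid(as.numeric(params$W_f %*% z) + params$b_f)
  q <- tanh(as.numeric(params$W_q %*% z) + params$b_q)
  o <- sigmoid(as.numeric(params$W_o %*% z) + params$b_o)
  cc <- f * state$c + i * q
  tc <- tanh(cc)
  h <- o * tc
  list(h = h, c = cc,
       gates = list(i = i, f = f, q = q, o = o, tanh_c = tc, z = z,
                    c_prev = state$c))
}

#' Analytic gradients of one LSTM step
#'
#' Given upstream gradients `dh` and `dc` on the step outputs, returns
#' gradients with respect to every parameter, the input, and the previous
#' state. Verified against central finite differences in the test suite.
#'
#' @param step result of [lstm_step()] (with its `gates` cache).
#' @param params the `dclstm_lstm_params` used.
#' @param dh,dc upstream gradients (length `d`).
#' @return list with `dW_i`, `dW_f`, `dW_q`, `dW_o`, `db_*`, `dx`,
#'   `dh_prev`, `dc_prev`.
#' @export
lstm_step_backward <- function(step, params, dh, dc = numeric(params$d)) {
  g <- step$gates
  d <- params$d
  dc_total <- dc + dh * g$o * (1 - g$tanh_c^2)
  do <- dh * g$tanh_c
  di <- dc_total * g$q
  dq <- dc_total * g$i
  df <- dc_total * g$c_prev
  dai <- di * g$i * (1 - g$i)
  daf <- df * g$f * (1 - g$f)
  dao <- do * g$o * (1 - g$o)
  daq <- dq * (1 - g$q^2)
  dz <- as.numeric(t(params$W_i) %*% dai + t(params$W_f) %*% daf +
                   t(params$W_q) %*% daq + t(params$W_o) %*% dao)
  list(dW_i = outer(dai, g$z), dW_f = outer(daf, g$z),
       dW_q = outer(daq, g$z), dW_o = outer(dao, g$z),
       db_i = dai, db_f = daf, db_q = daq, db_o = dao,
       dh_prev = dz[seq_len(d)], dx = dz[-seq_len(d)],
       dc_prev = dc_total * g$f)
}

#' Run an LSTM over a full sequence
#'
#' Both the hidden-state and cell-state sequences are returned because the
#' hybrid attention layer consumes the cell state at every time step.
#'
#' @param X `T x e` input matrix (rows are time steps).
#' @param params a `dclstm_lstm_params`.
#' @param h0,c0 initial state (default zero vectors).
#' @return list with `H` and `C`, both `T x d` matrices (0-row for `T = 0`).
#' @export
lstm_sequence <- function(X, params, h0 = NULL, c0 = NULL) {
  d <- params$d
  Tn <- nrow(X)
  state <- list(h = if (is.null(h0)) numeric(d) else h0,
                c = if (is.null(c0)) numeric(d) else c0)
  H <- matrix(0, Tn, d)
  C <- matrix(0, Tn, d)
  for (t in seq_len(Tn)) {
    state <- lstm_step(X[t, ], state, params)
    H[t, ] <- state$h
    C[t, ] <- state$c
  }
  list(H = H, C = C)
}

#' Construct hybrid-attention parameters
#'
#' The attention key at time `t` is the concatenation of hidden and cell
#' state, `[h_t; c_t]` (dimension `2d`); scores are
#' `e_t = v_a' tanh(W_a [h_t; c_t] + b)`.
#'
#' @param a attention dimension (defaults to `d`).
#' @param d LSTM hidden dimension.
#' @param init `"glorot"` or `"zero"`.
#' @return list of class `dclstm_attn_params` with `W_a` (`a x 2d`), `v_a`
#'   (length `a`), `b` (length `a`).
#' @export
attn_params <- function(a = NULL, d, init = "glorot") {
  if (is.null(a)) a <- d
  structure(list(a = as.integer(a), d = as.integer(d),
                 W_a = if (init == "zero") matrix(0, a, 2L * d) else glorot(a, 2L * d),
                 v_a = if (init == "zero") numeric(a) else stats::runif(a, -0.1, 0.1),
                 b = numeric(a)),
            class = "dclstm_attn_params")
}

#' Hybrid attention over LSTM hidden and cell states
#'
#' Keys are `k_t = [h_t; c_t]`; scores `e_t = v_a' tanh(W_a k_t + b)`;
#' weights `w = softmax(e)` (max-subtracted); the context is the weighted sum
#' of the concatenated keys, `context = sum_t w_t k_t` (dimension `2d`).
#'
#' @param H,C `T x d` matrices from [lstm_sequence()].
#' @param params a `dclstm_attn_params`.
#' @return list with `scores` (length `T`), `weights` (length `T`, sums to
#'   1), `context` (length `2d`), and a cache `S` of tanh activations.
#' @export
hybrid_attention <- function(H, C, params) {
  Tn <- nrow(H)
  if (Tn == 0L) stop_dclstm("hybrid attention needs a non-empty sequence")
  stopifnot(all(dim(H) == dim(C)))
  K <- cbind(H, C)                              # T x 2d
  S <- tanh(K %*% t(params$W_a) +
              matrix(params$b, Tn, params$a, byrow = TRUE))  # T x a
  e <- as.numeric(S %*% params$v_a)
  w <- as.numeric(softmax(e))
  context <- as.numeric(t(K) %*% w)
  list(scores = e, weights = w, context = context, S = S, K = K)
}

#' Analytic gradients of hybrid attention
#'
#' Given the upstream gradient on the context vector, returns gradients with
#' respect to `W_a`, `v_a`, `b`, `H` and `C`. Verified against central
#' finite differences in the test suite.
#'
#' @param att result of [hybrid_attention()].
#' @param params the `dclstm_attn_params` used.
#' @param dcontext upstream gradient, length `2d`.
#' @return list with `dW_a`, `dv_a`, `db`, `dH`, `dC`.
#' @export
hybrid_attention_backward <- function(att, params, dcontext) {
  K <- att$K
  w <- att$weights
  S <- att$S
  dK <- w %o% dcontext                          # T x 2d (context term)
  dw <- as.numeric(K %*% dcontext)
  de <- w * (dw - sum(dw * w))                  # softmax Jacobian
  dS <- (de %o% params$v_a) * (1 - S^2)         # T x a
  dW_a <- t(dS) %*% K
  db <- colSums(dS)
  dv_a <- as.numeric(t(S) %*% de)
  dK <- dK + dS %*% params$W_a
  d <- params$d
  list(dW_a = dW_a, dv_a = dv_a, db = db,
       dH = dK[, seq_len(d), drop = FALSE],
       dC = dK[, d + seq_len(d), drop = FALSE])
}

#' Construct GRU parameters (baseline cell)
#'
#' Update gate `z`, reset gate `r`, candidate `n`:
#' `z = sigmoid(W_z [h,x] + b_z)`, `r = sigmoid(W_r [h,x] + b_r)`,
#' `n = tanh(W_n [r*h, x] + b_n)`, `h_t = (1-z)*h_prev + z*n`.
#'
#' @param d hidden dimension.
#' @param e input dimension.
#' @param init `"glorot"` or `"zero"`.
#' @return list of class `dclstm_gru_params`.
#' @export
gru_params <- function(d, e, init = "glorot") {
  mk <- function() if (init == "zero") matrix(0, d, d + e) else glorot(d, d + e)
  structure(list(d = as.integer(d), e = as.integer(e),
                 W_z = mk(), W_r = mk(), W_n = mk(),
                 b_z = numeric(d), b_r = numeric(d), b_n = numeric(d)),
            class = "dclstm_gru_params")
}

#' Run a GRU over a sequence
#'
#' @param X `T x e` input matrix.
#' @param params a `dclstm_gru_params`.
#' @param h0 initial hidden state (default zeros).
#' @return list with `H` (`T x d`).
#' @export
gru_sequence <- function(X, params, h0 = NULL) {
  d <- params$d
  Tn <- nrow(X)
  h <- if (is.null(h0)) numeric(d) else h0
  H <- matrix(0, Tn, d)
  for (t in seq_len(Tn)) {
    x <- X[t, ]
    zin <- c(h, x)
    z <- sigmoid(as.numeric(params$W_z %*% zin) + params$b_z)
    r <- sigmoid(as.numeric(params$W_r %*% zin) + params$b_r)
    n <- tanh(as.numeric(params$W_n %*% c(r * h, x)) + params$b_n)
    h <- (1 - z) * h + z * n
    H[t, ] <- h
  }
  list(H = H)
}
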