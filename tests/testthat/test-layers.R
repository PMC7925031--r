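test_that("conv_output_length matches the closed form and rejects bad geometry", {
  expect_identical(conv_output_length(10, 3, 0, 1), 8L)
  expect_identical(conv_output_length(13, 1, 0, 1), 13L)
  expect_identical(conv_output_length(7, 3, 1, 2), 4L)
  expect_error(conv_output_length(2, 5, 0, 1), "invalid geometry")
})

test_that("convolve reproduces hand cases", {
  p <- conv_params(widths = 2L, n_maps = 1L, in_dim = 1L, init = "zero")
  p$kernels[["2"]] <- matrix(c(1, 1), 2, 1)
  out <- convolve(matrix(1, 4, 1), p)
  expect_equal(as.numeric(out[["2"]]), c(2, 2, 2))
  # all-zero kernel, bias 5 -> all outputs 5
  pz <- conv_params(widths = 3L, n_maps = 2L, in_dim = 2L, init = "zero")
  pz$bias[["3"]] <- c(5, 5)
  outz <- convolve(matrix(rnorm(12), 6, 2), pz)
  expect_equal(as.numeric(outz[["3"]]), rep(5, 8))
  expect_error(convolve(matrix(0, 4, 3), p), "channels")
})

test_that("convolve matches the nested-loop oracle with stride and padding", {
  for (seed in 1:10) {
    set.seed(seed)
    s0 <- sample(1:2, 1); pd <- sample(0:2, 1)
    prm <- random_conv_params(c(2L, 3L), n_maps = 2L, in_dim = 3L,
                              seed = seed + 100, stride = s0, padding = pd)
    x <- matrix(rnorm(24), 8, 3)
    got <- convolve(x, prm)
    want <- oracle_conv(x, prm)
    for (key in names(want)) expect_equal(got[[key]], want[[key]], tolerance = 1e-10)
  }
})

test_that("pool covers max-over-time, average, p-norm, and its limit", {
  expect_equal(pool(c(1, 3, 2, 8), pool_config()), 8)
  expect_equal(pool(c(2, 2, 2, 2), pool_config(2, 2, exponent = 1)), c(2, 2))
  expect_equal(pool(c(1, 2, 3, 4), pool_config(4, exponent = 64)), 4,
               tolerance = 1e-3)
  # the p-norm formula approaches the max as the exponent grows
  set.seed(3)
  x <- runif(6, 0.1, 2)
  expect_equal(pool(x, pool_config(6, exponent = 64)), max(x), tolerance = 1e-3)
  expect_equal(pool(x, pool_config(3, 3, exponent = 2)),
               oracle_pool(x, 3, 3, 2))
  expect_error(pool(c(1, 2), pool_config(5)), "window")
  expect_error(pool(c(-1, 2), pool_config(2, exponent = 2)), "non-negative")
})

test_that("lstm_step zero-parameter and saturation limits are exact", {
  d <- 4L; e <- 3L
  p0 <- lstm_params(d, e, forget_bias = 0, init = "zero")
  st <- lstm_step(rnorm(e), list(h = numeric(d), c = numeric(d)), p0)
  expect_equal(st$gates$i, rep(0.5, d))
  expect_equal(st$gates$f, rep(0.5, d))
  expect_equal(st$gates$o, rep(0.5, d))
  expect_equal(st$gates$q, rep(0, d))
  expect_equal(st$h, rep(0, d))
  expect_equal(st$c, rep(0, d))
  # saturated forget gate, closed input gate: pure memory
  pm <- lstm_params(d, e, forget_bias = 30, init = "zero")
  pm$b_i <- rep(-30, d)
  c_prev <- rnorm(d)
  st2 <- lstm_step(rnorm(e), list(h = numeric(d), c = c_prev), pm)
  expect_equal(st2$c, c_prev, tolerance = 1e-9)
  expect_error(lstm_step(c(NA, 1, 2), list(h = numeric(d), c = numeric(d)), p0),
               "non-finite")
})

test_that("lstm_step and lstm_sequence match the scalar-loop oracle", {
  for (seed in 1:10) {
    p <- random_lstm_params(3L, 2L, seed)
    set.seed(seed + 50)
    x <- rnorm(2); h0 <- rnorm(3); c0 <- rnorm(3)
    got <- lstm_step(x, list(h = h0, c = c0), p)
    want <- oracle_lstm_step(x, h0, c0, p)
    expect_equal(got$h, want$h, tolerance = 1e-6)
    expect_equal(got$c, want$c, tolerance = 1e-6)
    X <- matrix(rnorm(10), 5, 2)
    gseq <- lstm_sequence(X, p)
    wseq <- oracle_lstm_sequence(X, p)
    expect_equal(gseq$H, wseq$H, tolerance = 1e-6)
    expect_equal(gseq$C, wseq$C, tolerance = 1e-6)
  }
})

test_that("lstm_sequence equals chained lstm_step calls and handles T=0", {
  p <- random_lstm_params(3L, 2L, 77)
  X <- matrix(rnorm(8), 4, 2)
  seq <- lstm_sequence(X, p)
  st <- list(h = numeric(3), c = numeric(3))
  for (t in 1:4) {
    st <- lstm_step(X[t, ], st, p)
    expect_equal(seq$H[t, ], st$h)
    expect_equal(seq$C[t, ], st$c)
  }
  empty <- lstm_sequence(matrix(0, 0, 2), p)
  expect_identical(dim(empty$H), c(0L, 3L))
})

test_that("lstm hidden state is bounded by 1 in magnitude", {
  for (seed in 1:20) {
    p <- random_lstm_params(4L, 3L, seed)
    set.seed(seed)
    X <- matrix(rnorm(30, sd = 10), 10, 3)   # large inputs included
    H <- lstm_sequence(X, p)$H
    expect_true(all(abs(H) <= 1 + 1e-12))
  }
})

test_that("hybrid_attention singleton and zero-score symmetry are exact", {
  p <- random_attn_params(3L, 2L, 5)
  H <- matrix(rnorm(2), 1, 2); C <- matrix(rnorm(2), 1, 2)
  at <- hybrid_attention(H, C, p)
  expect_equal(at$weights, 1)
  expect_equal(at$context, c(H[1, ], C[1, ]))
  # W_a = 0, b = 0 -> equal scores -> uniform weights -> mean context
  p0 <- random_attn_params(3L, 2L, 6)
  p0$W_a[] <- 0; p0$b[] <- 0
  H4 <- matrix(rnorm(8), 4, 2); C4 <- matrix(rnorm(8), 4, 2)
  at4 <- hybrid_attention(H4, C4, p0)
  expect_equal(at4$weights, rep(0.25, 4))
  expect_equal(at4$context, colMeans(cbind(H4, C4)))
  expect_error(hybrid_attention(matrix(0, 0, 2), matrix(0, 0, 2), p),
               "non-empty")
})

test_that("hybrid_attention matches the loop oracle", {
  for (seed in 1:10) {
    p <- random_attn_params(3L, 2L, seed)
    set.seed(seed + 10)
    H <- matrix(rnorm(8), 4, 2); C <- matrix(rnorm(8), 4, 2)
    got <- hybrid_attention(H, C, p)
    want <- oracle_attention(H, C, p)
    expect_equal(got$weights, want$weights, tolerance = 1e-9)
    expect_equal(got$context, want$context, tolerance = 1e-9)
  }
})

test_that("analytic layer gradients match central finite differences", {
  fd_check <- function(fval, get, set, analytic, h = 1e-5, tol = 1e-4) {
    p <- get()
    for (i in seq_along(p)) {
      set(replace(p, i, p[i] + h)); up <- fval()
      set(replace(p, i, p[i] - h)); dn <- fval()
      set(p)
      fd <- (up - dn) / (2 * h)
      expect_equal(analytic[i], fd, tolerance = tol)
    }
  }
  # attention: loss = sum(dctx * context)
  p <- random_attn_params(2L, 2L, 31)
  set.seed(31)
  H <- matrix(rnorm(6), 3, 2); C <- matrix(rnorm(6), 3, 2)
  dctx <- rnorm(4)
  bwd <- hybrid_attention_backward(hybrid_attention(H, C, p), p, dctx)
  env <- environment()
  for (nm in c("W_a", "v_a", "b")) {
    fd_check(function() sum(dctx * hybrid_attention(H, C, p)$context),
             function() env$p[[nm]],
             function(v) { pp <- env$p; pp[[nm]][] <- v; env$p <- pp },
             as.numeric(bwd[[paste0("d", nm)]]))
  }
  fd_check(function() sum(dctx * hybrid_attention(H, C, p)$context),
           function() env$H, function(v) { env$H <- matrix(v, 3, 2) },
           as.numeric(bwd$dH))
  # lstm step: loss = sum(dh*h) + sum(dc*c)
  lp <- random_lstm_params(2L, 2L, 32)
  set.seed(32)
  x <- rnorm(2); h0 <- rnorm(2); c0 <- rnorm(2)
  dh <- rnorm(2); dc <- rnorm(2)
  st <- lstm_step(x, list(h = h0, c = c0), lp)
  lbwd <- lstm_step_backward(st, lp, dh, dc)
  lval <- function() {
    s <- lstm_step(x, list(h = h0, c = c0), env$lp)
    sum(dh * s$h) + sum(dc * s$c)
  }
  for (nm in c("W_i", "W_f", "W_q", "W_o", "b_i", "b_f", "b_q", "b_o")) {
    fd_check(lval, function() env$lp[[nm]],
             function(v) { pp <- env$lp; pp[[nm]][] <- v; env$lp <- pp },
             as.numeric(lbwd[[paste0("d", nm)]]))
  }
  fd_check(lval, function() env$x, function(v) env$x <- v,
           as.numeric(lbwd$dx))
})

test_that("gru_sequence reduces to a hand-computable scalar case", {
  # d = e = 1, all weights zero except biases: z = sigmoid(bz), n = tanh(bn)
  p <- gru_params(1L, 1L, init = "zero")
  p$b_z <- 0.3; p$b_n <- 0.5
  H <- gru_sequence(matrix(c(1, 2), 2, 1), p)$H
  z <- 1 / (1 + exp(-0.3)); n <- tanh(0.5)
  h1 <- z * n
  h2 <- (1 - z) * h1 + z * n
  expect_equal(as.numeric(H), c(h1, h2), tolerance = 1e-12)
})
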