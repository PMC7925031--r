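## Training: cross-entropy losses, Adam / Adadelta, and the mini-batch loop.
## One global seed drives initialization, shuffling and dropout; exact
## determinism holds within one hardware/BLAS-thread configuration.

#' Training configuration
#'
#' Defaults follow the published configuration (batch size 256, dropout
#' 0.25, Adam); the learning rate is an artifact default since the source
#' configuration's learning-rate row names an optimizer instead.
#'
#' @param batch_size mini-batch size.
#' @param optimizer `"adam"` or `"adadelta"`.
#' @param learning_rate step size (Adam); Adadelta ignores it and uses its
#'   own unit-free rule.
#' @param epochs training epochs.
#' @param seed global seed (initialization, shuffling, dropout).
#' @param loss `"categorical_ce"` or `"binary_ce"`.
#' @param val_fraction fraction of the training set held out for validation
#'   (0 disables the split and validates on the training data).
#' @param verbose print one line per epoch?
#' @return named list of class `dclstm_train_config`.
#' @export
train_config <- function(batch_size = 256L, optimizer = c("adam", "adadelta"),
                         learning_rate = 1e-3, epochs = 10L, seed = 1L,
                         loss = c("categorical_ce", "binary_ce"),
                         val_fraction = 0, verbose = FALSE) {
  optimizer <- match.arg(optimizer)
  loss <- match.arg(loss)
  if (batch_size < 1L) stop_dclstm("batch_size must be >= 1")
  structure(list(batch_size = as.integer(batch_size), optimizer = optimizer,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 seed = as.integer(seed), loss = loss,
                 val_fraction = val_fraction, verbose = isTRUE(verbose)),
            class = "dclstm_train_config")
}

#' Cross-entropy loss for one predicted distribution
#'
#' `categorical_ce` is `-log p[label]`; `binary_ce` is the mean over classes
#' of the per-class Bernoulli cross-entropy against the one-hot target.
#' Probabilities are clamped at 1e-12 (with a warning) rather than erroring.
#'
#' @param probs probability vector.
#' @param label 0-based class id.
#' @param kind `"categorical_ce"` or `"binary_ce"`.
#' @return non-negative scalar.
#' @export
loss_example <- function(probs, label, kind = c("categorical_ce", "binary_ce")) {
  kind <- match.arg(kind)
  clamped <- if (kind == "categorical_ce") probs[label + 1L] < 1e-12
             else any(probs < 1e-12 | probs > 1 - 1e-12)
  if (clamped) warning("probabilities clamped at 1e-12 in loss", call. = FALSE)
  probs <- pmin(pmax(probs, 1e-12), 1 - 1e-12)
  y <- rep(0, length(probs)); y[label + 1L] <- 1
  if (kind == "categorical_ce") -log(probs[label + 1L])
  else -mean(y * log(probs) + (1 - y) * log(1 - probs))
}

## batch loss and gradient on the logits (through the softmax)
batch_loss_grad <- function(probs, labels, kind) {
  B <- nrow(probs); C <- ncol(probs)
  p <- pmin(pmax(probs, 1e-12), 1 - 1e-12)
  Y <- matrix(0, B, C)
  Y[cbind(seq_len(B), labels + 1L)] <- 1
  if (kind == "categorical_ce") {
    loss <- -mean(log(p[cbind(seq_len(B), labels + 1L)]))
    dlogits <- (probs - Y) / B
  } else {
    loss <- -mean(Y * log(p) + (1 - Y) * log(1 - p))
    dLdp <- (-Y / p + (1 - Y) / (1 - p)) / (B * C)
    dlogits <- probs * (dLdp - rowSums(dLdp * probs))
  }
  list(loss = loss, dlogits = dlogits)
}

make_optimizer <- function(kind, params, lr) {
  zeros_like <- function(p) lapply(p, function(x) {
    if (is.null(dim(x))) numeric(length(x)) else array(0, dim = dim(x))
  })
  state <- list(kind = kind, lr = lr, t = 0L,
                m = zeros_like(params), v = zeros_like(params))
  state
}

optimizer_step <- function(opt, params, grads, updatable) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  rho <- 0.95; eps_ad <- 1e-6
  opt$t <- opt$t + 1L
  for (nm in updatable) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (opt$kind == "adam") {
      opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
      opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g^2
      mhat <- opt$m[[nm]] / (1 - b1^opt$t)
      vhat <- opt$v[[nm]] / (1 - b2^opt$t)
      params[[nm]] <- params[[nm]] - opt$lr * mhat / (sqrt(vhat) + eps)
    } else {                       # adadelta: m = E[g^2], v = E[dx^2]
      opt$m[[nm]] <- rho * opt$m[[nm]] + (1 - rho) * g^2
      dx <- -sqrt(opt$v[[nm]] + eps_ad) / sqrt(opt$m[[nm]] + eps_ad) * g
      opt$v[[nm]] <- rho * opt$v[[nm]] + (1 - rho) * dx^2
      params[[nm]] <- params[[nm]] + dx
    }
  }
  list(opt = opt, params = params)
}

eval_split <- function(model, data, loss_kind, batch_size = 256L) {
  probs <- predict_proba(model, data, batch_size)
  lg <- batch_loss_grad(probs, data$labels, loss_kind)
  preds <- max.col(probs, ties.method = "first") - 1L
  list(loss = lg$loss, accuracy = mean(preds == data$labels))
}

subset_data <- function(data, idx) {
  list(word_ids = if (!is.null(data$word_ids)) data$word_ids[idx, , drop = FALSE],
       char_ids = if (!is.null(data$char_ids)) data$char_ids[idx, , drop = FALSE],
       labels = data$labels[idx])
}

#' Train a model
#'
#' Mini-batch gradient descent with the configured optimizer. The history
#' records train (and validation) loss and accuracy per epoch; the best
#' validation checkpoint (by accuracy, loss as tie-break) is retained and
#' returned alongside the final parameters.
#'
#' @param model a `dclstm_model`.
#' @param data list with `word_ids`, `char_ids`, `labels` (from
#'   [encode_corpus()]); channels the architecture ignores may be NULL.
#' @param config a [train_config()].
#' @param val_data optional explicit validation split (same structure).
#' @return list with `model` (best-validation parameters), `final_model`,
#'   `history` (data.frame: epoch, split, loss, accuracy).
#' @export
train_model <- function(model, data, config, val_data = NULL) {
  st <- model$structure
  n <- length(data$labels)
  if (n == 0L) stop_dclstm("empty training set")
  if (any(data$labels < 0L | data$labels >= model$config$n_classes)) {
    stop_dclstm("labels out of range for n_classes=%d", model$config$n_classes)
  }
  set.seed(sub_seed(config$seed, 47L))
  if (is.null(val_data) && config$val_fraction > 0) {
    n_val <- max(1L, floor(config$val_fraction * n))
    vidx <- sample.int(n, n_val)
    val_data <- subset_data(data, vidx)
    data <- subset_data(data, setdiff(seq_len(n), vidx))
    n <- length(data$labels)
  }
  updatable <- setdiff(names(model$params),
                       setdiff(grep("_embed$", names(model$params), value = TRUE),
                               model$trainable_embeddings))
  opt <- make_optimizer(config$optimizer, model$params[updatable],
                        config$learning_rate)
  history <- list()
  best <- list(acc = -Inf, loss = Inf, params = model$params)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    i <- 1L
    epoch_loss <- 0; n_batches <- 0L
    while (i <= n) {
      j <- min(i + config$batch_size - 1L, n)
      idx <- ord[i:j]
      batch <- subset_data(data, idx)
      fwd <- model_forward_batch(model,
                                 batch$word_ids, batch$char_ids, train = TRUE)
      lg <- batch_loss_grad(fwd$probs, batch$labels, config$loss)
      if (!is.finite(lg$loss)) {
        stop_dclstm("divergent loss (%g) at epoch %d", lg$loss, epoch)
      }
      grads <- model_backward_batch(model, fwd, lg$dlogits)
      stepped <- optimizer_step(opt, model$params, grads,
                                intersect(updatable, names(grads)))
      opt <- stepped$opt
      model$params <- stepped$params
      epoch_loss <- epoch_loss + lg$loss
      n_batches <- n_batches + 1L
      i <- j + 1L
    }
    tr <- eval_split(model, data, config$loss, config$batch_size)
    history[[length(history) + 1L]] <-
      data.frame(epoch = epoch, split = "train",
                 loss = tr$loss, accuracy = tr$accuracy)
    va <- tr
    if (!is.null(val_data)) {
      va <- eval_split(model, val_data, config$loss, config$batch_size)
      history[[length(history) + 1L]] <-
        data.frame(epoch = epoch, split = "validation",
                   loss = va$loss, accuracy = va$accuracy)
    }
    if (va$accuracy > best$acc ||
        (va$accuracy == best$acc && va$loss < best$loss)) {
      best <- list(acc = va$accuracy, loss = va$loss, params = model$params)
    }
    if (config$verbose) {
      message(sprintf("epoch %d  train loss %.4f acc %.4f  val loss %.4f acc %.4f",
                      epoch, tr$loss, tr$accuracy, va$loss, va$accuracy))
    }
  }
  final_model <- model
  best_model <- model
  best_model$params <- best$params
  list(model = best_model, final_model = final_model,
       history = do.call(rbind, history))
}
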