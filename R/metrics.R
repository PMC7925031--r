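## Evaluation: one-vs-rest confusion counts, precision/recall/F1/accuracy,
## macro averages, and rank-based (Mann-Whitney) one-vs-rest AUC.

#' One-vs-rest confusion counts per class
#'
#' For each class, that class is treated as positive and all others as
#' negative; TP+FP+TN+FN equals the number of examples for every class.
#'
#' @param predicted,actual equal-length integer vectors of 0-based labels.
#' @param n_classes number of classes.
#' @return data.frame with columns `class`, `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(predicted, actual, n_classes) {
  stopifnot(length(predicted) == length(actual))
  if (any(c(predicted, actual) < 0L) || any(c(predicted, actual) >= n_classes)) {
    stop_dclstm("labels out of range [0, %d)", n_classes)
  }
  n <- length(actual)
  out <- lapply(seq_len(n_classes) - 1L, function(k) {
    tp <- sum(predicted == k & actual == k)
    fp <- sum(predicted == k & actual != k)
    fn <- sum(predicted != k & actual == k)
    data.frame(class = k, TP = tp, FP = fp, TN = n - tp - fp - fn, FN = fn)
  })
  do.call(rbind, out)
}

safe_ratio <- function(num, den) ifelse(den == 0, 0, num / den)

#' Classification metrics from one-vs-rest confusion counts
#'
#' Per class (one-vs-rest): precision `TP/(TP+FP)`, recall `TP/(TP+FN)`,
#' accuracy `(TP+TN)/(TP+FP+TN+FN)`, and F1 as the harmonic mean of
#' precision and recall. The top-level `accuracy` is the pooled multiclass
#' accuracy — the fraction of examples whose predicted label is correct,
#' i.e. `sum(TP) / n` over a complete one-vs-rest count set. Macro scores
#' are unweighted means over classes. Undefined ratios (0/0) are reported
#' as 0 and flagged in `undefined`.
#'
#' @param counts data.frame from [confusion()].
#' @return list with `accuracy`, `per_class` (data.frame: class, precision,
#'   recall, f1, accuracy), `macro_precision`, `macro_recall`, `macro_f1`,
#'   `undefined` (logical: any 0/0 ratio encountered).
#' @export
compute_metrics <- function(counts) {
  n <- counts$TP[1] + counts$FP[1] + counts$TN[1] + counts$FN[1]
  prec <- safe_ratio(counts$TP, counts$TP + counts$FP)
  rec <- safe_ratio(counts$TP, counts$TP + counts$FN)
  f1 <- safe_ratio(2 * prec * rec, prec + rec)
  undefined <- any((counts$TP + counts$FP) == 0) ||
    any((counts$TP + counts$FN) == 0)
  list(accuracy = sum(counts$TP) / n,
       per_class = data.frame(class = counts$class, precision = prec,
                              recall = rec, f1 = f1,
                              accuracy = (counts$TP + counts$TN) / n),
       macro_precision = mean(prec), macro_recall = mean(rec),
       macro_f1 = mean(f1), undefined = undefined)
}

#' One-vs-rest ROC AUC via the rank statistic
#'
#' Midranks handle ties, so the result equals the probability that a random
#' positive outscores a random negative, counting ties as 1/2.
#'
#' @param scores matrix (`n x n_classes`) of per-class scores, or a vector
#'   of scores for the chosen class.
#' @param labels 0-based true labels.
#' @param class_id 0-based class treated as positive.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels, class_id) {
  s <- if (is.matrix(scores)) scores[, class_id + 1L] else scores
  pos <- labels == class_id
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop_dclstm("AUC undefined: class %d has %d positives and %d negatives",
                class_id, n_pos, n_neg)
  }
  r <- rank(s, ties.method = "average")
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Full evaluation report for a scored test set
#'
#' @param probs `n x n_classes` probability matrix.
#' @param labels 0-based true labels.
#' @return list combining [compute_metrics()] output with per-class `auc`
#'   (NA for classes without both positives and negatives).
#' @export
evaluate_predictions <- function(probs, labels) {
  n_classes <- ncol(probs)
  preds <- max.col(probs, ties.method = "first") - 1L
  counts <- confusion(preds, labels, n_classes)
  m <- compute_metrics(counts)
  m$auc <- vapply(seq_len(n_classes) - 1L, function(k) {
    if (sum(labels == k) == 0L || sum(labels != k) == 0L) return(NA_real_)
    roc_auc(probs, labels, k)
  }, numeric(1))
  m$counts <- counts
  m
}

#' Format an evaluation as a one-row report table
#'
#' Mirrors the standard comparison-table columns (model, dataset, accuracy,
#' precision, recall, F1) using macro averages.
#'
#' @param m result of [evaluate_predictions()].
#' @param model,dataset identifying strings.
#' @return one-row data.frame.
#' @export
metrics_report <- function(m, model = "dc_lstm", dataset = "synthetic") {
  data.frame(model = model, dataset = dataset,
             accuracy = m$accuracy, precision = m$macro_precision,
             recall = m$macro_recall, f1 = m$macro_f1)
}
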