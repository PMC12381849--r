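#' Flatten one-hot truths and predicted probabilities
#'
#' Converts aligned lists-of-lists into flat 0-based label vectors: the
#' predicted label is the argmax of each probability vector (ties broken
#' toward the lowest index) and the true label is the position of the
#' single 1 in each one-hot row.
#'
#' @param true_onehots n x m matrix with exactly one 1 per row.
#' @param pred_probabilities n x m matrix of class probabilities.
#' @return List with integer vectors `true` and `pred` (0-based).
#' @export
flatten_labels <- function(true_onehots, pred_probabilities) {
  true_onehots <- as.matrix(true_onehots)
  pred_probabilities <- as.matrix(pred_probabilities)
  stopifnot(nrow(true_onehots) == nrow(pred_probabilities))
  ones <- rowSums(true_onehots == 1)
  if (any(ones != 1) || any(!true_onehots %in% c(0, 1)))
    stop("each true vector must be one-hot (exactly one 1)")
  list(true = max.col(true_onehots, ties.method = "first") - 1L,
       pred = max.col(pred_probabilities, ties.method = "first") - 1L)
}

#' Class-indexed confusion matrix
#'
#' `C[i, j]` counts test instances with true class i predicted as class
#' j (0-based classes on both axes); all entries sum to the number of
#' test instances.
#'
#' @param true_indices,pred_indices 0-based label vectors.
#' @param m number of classes.
#' @return m x m integer matrix, dimnames the 0-based class indices.
#' @export
confusion_matrix <- function(true_indices, pred_indices, m) {
  stopifnot(length(true_indices) == length(pred_indices))
  if (any(c(true_indices, pred_indices) < 0L) ||
      any(c(true_indices, pred_indices) >= m))
    stop("label index outside 0..", m - 1L)
  C <- matrix(0L, m, m, dimnames = list(true = 0:(m - 1),
                                        pred = 0:(m - 1)))
  for (k in seq_along(true_indices)) {
    i <- true_indices[k] + 1L; j <- pred_indices[k] + 1L
    C[i, j] <- C[i, j] + 1L
  }
  C
}

#' Per-class TP/FP/FN/TN from a confusion matrix
#'
#' TP is the diagonal element; FP the column sum minus it; FN the row
#' sum minus it; TN the remainder, so the four always sum to the total
#' count.
#'
#' @param C confusion matrix.
#' @param class 0-based class index.
#' @return Named numeric vector `(TP, FP, FN, TN)`.
#' @export
per_class_counts <- function(C, class) {
  i <- class + 1L
  tp <- C[i, i]
  fp <- sum(C[, i]) - tp
  fn <- sum(C[i, ]) - tp
  tn <- sum(C) - tp - fp - fn
  c(TP = tp, FP = fp, FN = fn, TN = tn)
}

#' Overall accuracy and micro-averaged precision/recall/F1
#'
#' Accuracy is trace over total; the micro metrics pool TP/FP/FN across
#' classes before dividing. For single-label one-hot data every false
#' positive for one class is a false negative for another, so micro
#' precision, recall and F1 all equal the accuracy; this identity is a
#' useful self-check and holds here by construction.
#'
#' @param C confusion matrix with at least one entry.
#' @return Named list `accuracy`, `precision_micro`, `recall_micro`,
#'   `f1_micro`.
#' @export
micro_metrics <- function(C) {
  total <- sum(C)
  if (total == 0) stop("empty confusion matrix")
  counts <- vapply(seq_len(nrow(C)) - 1L, per_class_counts,
                   numeric(4), C = C)
  tp <- sum(counts["TP", ]); fp <- sum(counts["FP", ])
  fn <- sum(counts["FN", ])
  prec <- tp / (tp + fp)
  rec <- tp / (tp + fn)
  list(accuracy = sum(diag(C)) / total,
       precision_micro = prec, recall_micro = rec,
       f1_micro = 2 * prec * rec / (prec + rec))
}

#' Per-class top-k accuracy table
#'
#' For each class, the fraction of its instances whose true label ranks
#' within the k highest predicted probabilities (rank ties broken toward
#' the lowest class index, matching the argmax convention). top-k is
#' non-decreasing in k by construction; k larger than the class count is
#' clamped with a message.
#'
#' @param true_indices 0-based true labels.
#' @param pred_probabilities n x m probability matrix.
#' @param ks k values (default 1, 3, 5, 10).
#' @return Data frame with `class`, `support` and one `top<k>` column
#'   per k.
#' @export
topk_table <- function(true_indices, pred_probabilities,
                       ks = c(1L, 3L, 5L, 10L)) {
  P <- as.matrix(pred_probabilities)
  m <- ncol(P)
  if (any(ks > m)) {
    message("top-k with k > ", m, " clamped to ", m)
    ks <- pmin(ks, m)
  }
  ks <- sort(unique(as.integer(ks)))
  # rank of the true class in each row: 1 + number of classes ranked
  # strictly ahead; among equal probabilities lower indices rank first
  n <- nrow(P)
  rank_true <- vapply(seq_len(n), function(r) {
    j <- true_indices[r] + 1L
    pj <- P[r, j]
    sum(P[r, ] > pj) + sum(P[r, seq_len(j - 1L)] == pj) + 1L
  }, integer(1))
  classes <- sort(unique(true_indices))
  out <- data.frame(class = classes,
                    support = vapply(classes, function(cl)
                      sum(true_indices == cl), integer(1)))
  for (k in ks)
    out[[paste0("top", k)]] <- vapply(classes, function(cl)
      mean(rank_true[true_indices == cl] <= k), numeric(1))
  out
}

#' Count poorly characterized classes
#'
#' A class counts as poorly characterized at level k when its support
#' exceeds `min_support` and its top-k accuracy falls below `threshold`.
#'
#' @param per_class a [topk_table()] result.
#' @param k which top-k column to use.
#' @param min_support support must exceed this (default 10).
#' @param threshold top-k accuracy cutoff (default 0.10).
#' @return Integer count.
#' @export
count_poor_classes <- function(per_class, k, min_support = 10L,
                               threshold = 0.10) {
  col <- paste0("top", k)
  if (!col %in% names(per_class)) stop("no ", col, " column in table")
  sum(per_class$support > min_support & per_class[[col]] < threshold)
}

#' Full evaluation report
#'
#' Flattens labels, builds the confusion matrix and assembles overall
#' accuracy, micro-averaged metrics and the per-class top-k table in one
#' object.
#'
#' @param true_onehots n x m one-hot truth matrix (or 0-based class
#'   vector).
#' @param pred_probabilities n x m probability matrix.
#' @param ks top-k levels.
#' @return An object of class `eval_report`: list with `confusion`,
#'   `n_test`, `accuracy_overall`, `precision_micro`, `recall_micro`,
#'   `f1_micro`, `per_class`.
#' @export
eval_report <- function(true_onehots, pred_probabilities,
                        ks = c(1L, 3L, 5L, 10L)) {
  P <- as.matrix(pred_probabilities)
  if (is.matrix(true_onehots) && ncol(true_onehots) > 1) {
    fl <- flatten_labels(true_onehots, P)
  } else {
    fl <- list(true = as.integer(true_onehots),
               pred = max.col(P, ties.method = "first") - 1L)
  }
  m <- ncol(P)
  C <- confusion_matrix(fl$true, fl$pred, m)
  mm <- micro_metrics(C)
  structure(list(confusion = C, n_test = sum(C),
                 accuracy_overall = mm$accuracy,
                 precision_micro = mm$precision_micro,
                 recall_micro = mm$recall_micro,
                 f1_micro = mm$f1_micro,
                 per_class = topk_table(fl$true, P, ks)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> ", x$n_test, " test instances, ",
      nrow(x$confusion), " classes\n", sep = "")
  cat(sprintf("  accuracy %.3f | micro P %.3f R %.3f F1 %.3f\n",
              x$accuracy_overall, x$precision_micro, x$recall_micro,
              x$f1_micro))
  invisible(x)
}

#' Write an evaluation report as CSV files plus a text summary
#'
#' @param report an `eval_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_eval_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$confusion,
                   file.path(dir, "confusion_matrix.csv"))
  utils::write.csv(report$per_class, file.path(dir, "per_class.csv"),
                   row.names = FALSE)
  con <- file(file.path(dir, "summary.txt"), "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("test instances: %d", report$n_test),
    sprintf("accuracy: %.3f", report$accuracy_overall),
    sprintf("precision_micro: %.3f", report$precision_micro),
    sprintf("recall_micro: %.3f", report$recall_micro),
    sprintf("f1_micro: %.3f", report$f1_micro)), con)
  invisible(dir)
}
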