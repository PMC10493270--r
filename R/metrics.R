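#' Classification metrics (accuracy, recall, precision, F1, confusion)
#'
#' Accuracy is the overall fraction correct. For two classes, recall,
#' precision and F1 are the textbook TP/TN/FP/FN formulas computed for the
#' positive class (the last label in `labels`):
#' recall = TP/(TP+FN), precision = TP/(TP+FP),
#' F1 = 2 * precision * recall / (precision + recall).
#' With more classes the same per-class one-vs-rest values are macro-averaged
#' with equal class weight. A class never predicted gets precision 0 by
#' convention (and F1 0 when recall is also 0).
#'
#' @param y_true,y_pred Vectors of labels (character or factor), equal
#'   length.
#' @param labels Class-label universe and order; defaults to the sorted
#'   union of observed labels.
#' @return A `metrics_report`: list with `accuracy`, `recall`, `precision`,
#'   `f1`, `per_class` (data.frame) and `confusion` (rows = true class).
#' @export
compute_metrics <- function(y_true, y_pred,
                            labels = sort(unique(c(y_true, y_pred)))) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) stop("label vectors differ in length")
  bad <- setdiff(c(y_true, y_pred), labels)
  if (length(bad)) stop("label(s) outside class set: ",
                        paste(bad, collapse = ", "))
  tf <- factor(y_true, levels = labels)
  pf <- factor(y_pred, levels = labels)
  confusion <- table(true = tf, predicted = pf)
  per_class <- data.frame(label = labels, tp = NA_real_, fp = NA_real_,
                          fn = NA_real_, tn = NA_real_)
  for (i in seq_along(labels)) {
    tp <- confusion[i, i]
    fp <- sum(confusion[-i, i])
    fn <- sum(confusion[i, -i])
    per_class[i, 2:5] <- c(tp, fp, fn, sum(confusion) - tp - fp - fn)
  }
  prec <- ifelse(per_class$tp + per_class$fp > 0,
                 per_class$tp / (per_class$tp + per_class$fp), 0)
  rec <- ifelse(per_class$tp + per_class$fn > 0,
                per_class$tp / (per_class$tp + per_class$fn), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  per_class$precision <- prec
  per_class$recall <- rec
  per_class$f1 <- f1
  if (length(labels) == 2) {
    k <- 2  # positive class = second label
    out <- list(accuracy = sum(diag(confusion)) / sum(confusion),
                recall = rec[k], precision = prec[k], f1 = f1[k])
  } else {
    out <- list(accuracy = sum(diag(confusion)) / sum(confusion),
                recall = mean(rec), precision = mean(prec), f1 = mean(f1))
  }
  structure(c(out, list(per_class = per_class,
                        confusion = unclass(confusion))),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f | recall %.4f | precision %.4f | F1 %.4f\n",
              x$accuracy, x$recall, x$precision, x$f1))
  print(x$confusion)
  invisible(x)
}

#' One-vs-rest ROC AUC per class
#'
#' Mann-Whitney AUC (rank statistic with midrank tie handling): for each
#' class, the probability that a random member of the class outscores a
#' random non-member under that class's score column. A constant scorer
#' yields 0.5; a perfect scorer 1.0.
#'
#' @param y_true Label vector.
#' @param scores Numeric matrix, one column per class (named, or ordered as
#'   `labels`).
#' @param labels Class-label order; defaults to column names of `scores`.
#' @return Named numeric vector of per-class AUC values.
#' @export
roc_auc <- function(y_true, scores, labels = colnames(scores)) {
  scores <- as.matrix(scores)
  if (is.null(labels)) labels <- sort(unique(as.character(y_true)))
  if (!all(is.finite(scores))) stop("scores must be finite")
  if (length(unique(y_true)) < 2) {
    stop("AUC undefined: y_true contains a single class")
  }
  vapply(seq_along(labels), function(i) {
    pos <- as.character(y_true) == labels[i]
    s <- scores[, i]
    r <- rank(s)                       # midranks handle ties
    n1 <- sum(pos)
    n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) return(NA_real_)
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1), USE.NAMES = FALSE) -> auc
  names(auc) <- labels
  auc
}

#' Subject-exclusive, class-stratified fold assignment
#'
#' Partitions subjects (not samples) into `k` folds so that all of a
#' subject's segments share a fold, preventing identity leakage across the
#' train/test boundary. Within each class, subjects are shuffled and dealt
#' round-robin, stratifying class composition as far as integer counts
#' allow.
#'
#' @param subject_ids Character vector of subject IDs (one entry per subject
#'   or per sample; duplicates are collapsed).
#' @param subject_labels Class label of each entry of `subject_ids`.
#' @param k Number of folds.
#' @param seed RNG seed for the shuffle.
#' @return A `fold_plan`: list with `k` and named integer vector
#'   `assignments` (subject -> fold).
#' @export
make_subject_folds <- function(subject_ids, subject_labels, k = 10,
                               seed = 1) {
  keep <- !duplicated(subject_ids)
  subjects <- subject_ids[keep]
  labs <- subject_labels[keep]
  if (length(subjects) < k) {
    stop("fewer subjects (", length(subjects), ") than folds (", k, ")")
  }
  assignments <- integer(length(subjects))
  names(assignments) <- subjects
  with_seed(seed, {
    offset <- 0
    for (lab in unique(labs)) {
      idx <- sample(which(labs == lab))
      assignments[idx] <- ((offset + seq_along(idx) - 1) %% k) + 1
      offset <- offset + length(idx)
    }
  })
  structure(list(k = as.integer(k), assignments = assignments),
            class = "fold_plan")
}
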