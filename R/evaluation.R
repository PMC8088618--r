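## Evaluation: confusion-matrix metrics, AUROC, AUPRC, Wilcoxon signed-rank
## comparison and the cross-validation driver.

#' Confusion counts from labels and predictions
#'
#' @param labels true 0/1 labels.
#' @param predicted predicted 0/1 labels.
#' @return List of class `confusion_counts` with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(labels, predicted) {
  check_that(length(labels) == length(predicted), "length mismatch")
  structure(list(TP = sum(labels == 1 & predicted == 1),
                 TN = sum(labels == 0 & predicted == 0),
                 FP = sum(labels == 0 & predicted == 1),
                 FN = sum(labels == 1 & predicted == 0)),
            class = "confusion_counts")
}

#' Precision, recall, F-measure and accuracy
#'
#' `recall = TP/(TP+FN)`, `precision = TP/(TP+FP)`,
#' `F = 2*recall*precision/(recall+precision)`,
#' `accuracy = (TP+TN)/total`. Conventions: precision/recall are 0 when
#' their denominator is 0, and F is 0 when precision + recall = 0.
#'
#' @param counts a [confusion_counts()] object.
#' @return Named list: `precision`, `recall`, `f_measure`, `accuracy`.
#' @export
classification_metrics <- function(counts) {
  total <- counts$TP + counts$TN + counts$FP + counts$FN
  check_that(total > 0, "no evaluated pairs")
  prec <- if (counts$TP + counts$FP > 0) counts$TP / (counts$TP + counts$FP)
          else 0
  rec <- if (counts$TP + counts$FN > 0) counts$TP / (counts$TP + counts$FN)
         else 0
  f <- if (prec + rec > 0) 2 * rec * prec / (rec + prec) else 0
  list(precision = prec, recall = rec, f_measure = f,
       accuracy = (counts$TP + counts$TN) / total)
}

#' Area under the ROC curve
#'
#' Computed by the rank (Mann-Whitney) identity: the probability that a
#' random positive is scored above a random negative, ties counted 1/2.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return Real in [0, 1].
#' @export
auroc <- function(scores, labels) {
  check_that(length(scores) == length(labels), "length mismatch")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUROC undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Average-precision stepping: sum over distinct score thresholds (descending)
#' of the recall increment times the precision at that threshold. This avoids
#' the optimistic linear interpolation of trapezoidal PR integration.
#'
#' @inheritParams auroc
#' @param interpolation `"step"` (average precision, default) or
#'   `"trapezoid"`.
#' @return Real in (0, 1].
#' @export
auprc <- function(scores, labels, interpolation = c("step", "trapezoid")) {
  interpolation <- match.arg(interpolation)
  check_that(length(scores) == length(labels), "length mismatch")
  n_pos <- sum(labels == 1)
  if (n_pos == 0) stop("AUPRC undefined without positives", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y == 1)
  fp <- cumsum(y == 0)
  ## evaluate only at the last index of each tied score block
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  if (interpolation == "step") {
    sum(diff(c(0, rec)) * prec)
  } else {
    prev_r <- c(0, rec[-length(rec)])
    prev_p <- c(1, prec[-length(prec)])
    sum((rec - prev_r) * (prec + prev_p) / 2)
  }
}

#' Wilcoxon signed-rank test for paired performance samples
#'
#' Paired comparison of two models' per-fold metrics. Zero differences are
#' dropped (with a note in the result); the p-value is exact (signed-rank
#' enumeration distribution) for n <= 25 without tied absolute differences
#' and a continuity-corrected normal approximation otherwise. If every
#' difference is zero the p-value is 1 with a warning.
#'
#' @param a,b paired numeric vectors of equal length.
#' @param alternative `"two.sided"` (default), `"greater"` (a > b) or
#'   `"less"`.
#' @return List: `p_value`, `statistic` (V, rank sum of positive
#'   differences), `n_used` (pairs after dropping zeros), `alternative`.
#' @export
wilcoxon_signed_rank <- function(a, b,
                                 alternative = c("two.sided", "greater",
                                                 "less")) {
  alternative <- match.arg(alternative)
  check_that(length(a) == length(b) && length(a) >= 1,
             "`a` and `b` must be paired vectors of equal length >= 1")
  d <- a - b
  nz <- d != 0
  if (!any(nz)) {
    warning("all paired differences are zero; p = 1")
    return(list(p_value = 1, statistic = 0, n_used = 0L,
                alternative = alternative))
  }
  d <- d[nz]
  n <- length(d)
  exact <- n <= 25 && !any(duplicated(abs(d)))
  ht <- suppressWarnings(stats::wilcox.test(
    d, alternative = alternative, mu = 0, exact = exact, correct = TRUE))
  list(p_value = unname(ht$p.value), statistic = unname(ht$statistic),
       n_used = n, alternative = alternative)
}

#' Cross-validate a model mode over a fold assignment
#'
#' For each fold: trains on the fold's training pairs, predicts its test
#' pairs, and computes AUROC, AUPRC, F-measure and accuracy. Hard-mode
#' assignments are audited leakage-free before any training. The summary
#' reports mean and population SD over the k folds.
#'
#' @param pairs a [labeled_pairs()] set consistent with `folds`.
#' @param folds a `fold_assignment` from [split_baseline()],
#'   [split_unseen_compound()] or [split_hard()].
#' @param features as in [train_fusion()].
#' @param cfg a [training_config()].
#' @param mode model mode.
#' @return List of class `cv_result`: `per_fold` (data.frame with one row
#'   per fold), `summary` (mean/sd rows), `predictions` (per-fold test
#'   predictions, for model comparisons).
#' @export
cross_validate <- function(pairs, folds, features, cfg = training_config(),
                           mode = c("integrated", "molecular", "network")) {
  mode <- match.arg(mode)
  audit <- audit_leakage(folds)
  if (!audit$pass) {
    stop(sprintf("fold assignment fails its leakage audit (%s): %s",
                 folds$mode, paste(utils::head(audit$offenders, 5),
                                   collapse = ", ")), call. = FALSE)
  }
  rows <- vector("list", folds$k)
  preds <- vector("list", folds$k)
  for (i in 0:(folds$k - 1)) {
    tr <- train_pairs(folds, i)
    te <- test_pairs(folds, i)
    fit <- train_fusion(tr, features, cfg, mode = mode)
    pr <- predict(fit, te, features, threshold = cfg$threshold)
    cm <- classification_metrics(confusion_counts(te$label, pr$predicted))
    rows[[i + 1]] <- data.frame(
      fold = i, n_train = nrow(tr), n_test = nrow(te),
      auroc = auroc(pr$score, te$label), auprc = auprc(pr$score, te$label),
      f_measure = cm$f_measure, accuracy = cm$accuracy)
    pr$label <- te$label
    pr$fold <- i
    preds[[i + 1]] <- pr
  }
  per_fold <- do.call(rbind, rows)
  metr <- c("auroc", "auprc", "f_measure", "accuracy")
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  summary <- data.frame(
    statistic = c("mean", "sd"),
    rbind(vapply(per_fold[metr], mean, 0), vapply(per_fold[metr], pop_sd, 0)))
  structure(list(mode = mode, per_fold = per_fold, summary = summary,
                 predictions = do.call(rbind, preds)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cross-validation (%s mode, %d folds)\n", x$mode,
              nrow(x$per_fold)))
  print(x$per_fold, row.names = FALSE)
  print(x$summary, row.names = FALSE)
  invisible(x)
}
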