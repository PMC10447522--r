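# Model evaluation: precision/recall threshold sweeps, ROC/AUC and
# normalized feature importance.

#' Precision and recall across classification thresholds
#'
#' At each threshold t a bond is predicted SHB when its probability is
#' >= t. Precision = TP / (TP + FP) (reported as `NA` when nothing is
#' predicted positive), recall = TP / (TP + FN), false positive rate =
#' FP / (FP + TN).
#'
#' @param probabilities predicted SHB probabilities in [0, 1].
#' @param labels binary labels (1/0, or "SHB"/"NHB").
#' @param thresholds threshold grid; default is all distinct probabilities
#'   plus 0 and 1. Use `thresholds = "grid"` for a uniform 0.001-step grid.
#' @return data.frame with columns threshold, TP, FP, FN, TN, precision,
#'   recall, fpr.
#' @export
precision_recall <- function(probabilities, labels, thresholds = NULL) {
  y <- normalize_labels(labels)
  p <- probabilities
  if (length(p) != length(y))
    stop("probabilities and labels differ in length")
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  if (is.null(thresholds)) {
    thresholds <- sort(unique(c(0, p, 1)))
  } else if (identical(thresholds, "grid")) {
    thresholds <- seq(0, 1, by = 0.001)
  }
  out <- lapply(thresholds, function(t) {
    pred <- p >= t
    tp <- sum(pred & y == 1); fp <- sum(pred & y == 0)
    fn <- sum(!pred & y == 1); tn <- sum(!pred & y == 0)
    data.frame(threshold = t, TP = tp, FP = fp, FN = fn, TN = tn,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_)
  })
  do.call(rbind, out)
}

normalize_labels <- function(labels) {
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(as.integer(labels))
  }
  label_to_binary(labels)
}

#' ROC curve and AUC
#'
#' The ROC curve is evaluated at every distinct threshold; the AUC uses the
#' rank-statistic (Mann-Whitney) form, counting ties as one half, which is
#' identical to trapezoidal integration of the empirical curve.
#'
#' @inheritParams precision_recall
#' @return list with `roc` (data.frame threshold/fpr/recall) and `auc`.
#' @export
roc_auc <- function(probabilities, labels) {
  y <- normalize_labels(labels)
  p <- probabilities
  if (length(p) != length(y))
    stop("probabilities and labels differ in length")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present to compute a ROC curve")
  r <- rank(p, ties.method = "average")
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  sweep <- precision_recall(p, y)
  list(roc = sweep[, c("threshold", "fpr", "recall")], auc = auc)
}

#' Normalized feature importance of an ensemble
#'
#' Per member, the split-improvement (gain) of every tree split is summed
#' per encoded column, indicator columns are folded back onto their parent
#' categorical feature, and scores are normalized to sum to 100 percent.
#' The ensemble score is the mean over members. Features contributing less
#' than `group_below` percent can be grouped into an `"Other"` row.
#'
#' @param m fitted `shb_ensemble`.
#' @param group_below group features below this percentage into "Other";
#'   `NULL` (default) disables grouping.
#' @return data.frame with columns `feature` and `importance` (percent),
#'   sorted decreasing.
#' @export
feature_importance <- function(m, group_below = NULL) {
  if (!inherits(m, "shb_ensemble")) stop("need a fitted shb_ensemble")
  feats <- c(NUM_FEATURES, CAT_FEATURES)
  per_member <- vapply(ensemble_boosters(m), function(b) {
    imp <- xgboost::xgb.importance(model = b)
    v <- setNames(rep(0, length(feats)), feats)
    if (!is.null(imp) && nrow(imp) > 0) {
      parent <- sub("=.*$", "", imp$Feature)
      for (k in seq_len(nrow(imp))) {
        f <- parent[k]
        if (f %in% feats) v[f] <- v[f] + imp$Gain[k]
      }
    }
    if (sum(v) > 0) v <- 100 * v / sum(v)
    v
  }, numeric(length(feats)))
  score <- rowMeans(matrix(per_member, nrow = length(feats),
                           dimnames = list(feats)))
  out <- data.frame(feature = feats, importance = unname(score),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(group_below)) {
    small <- out$importance < group_below
    if (any(small)) {
      other <- data.frame(feature = "Other",
                          importance = sum(out$importance[small]),
                          stringsAsFactors = FALSE)
      out <- rbind(out[!small, , drop = FALSE], other)
      rownames(out) <- NULL
    }
  }
  out
}

#' Full evaluation report
#'
#' @param m fitted `shb_ensemble`.
#' @param test labeled feature table.
#' @param thresholds see [precision_recall()].
#' @param group_below see [feature_importance()].
#' @return list of class `shb_evaluation`: `sweep`, `roc`, `auc`,
#'   `importance`, and the operating point at the model threshold.
#' @export
evaluate_model <- function(m, test, thresholds = NULL, group_below = NULL) {
  p <- predict_proba(m, test)
  y <- label_to_binary(test$label)
  sweep <- precision_recall(p, y, thresholds)
  ra <- roc_auc(p, y)
  at <- precision_recall(p, y, thresholds = m$threshold)
  structure(list(sweep = sweep, roc = ra$roc, auc = ra$auc,
                 importance = feature_importance(m, group_below),
                 operating_point = at, threshold = m$threshold),
            class = "shb_evaluation")
}

#' @export
print.shb_evaluation <- function(x, ...) {
  op <- x$operating_point
  cat(sprintf("shb_evaluation: AUC %.3f\n", x$auc))
  cat(sprintf("at threshold %.3f: precision %s, recall %s\n", x$threshold,
              format(round(100 * op$precision, 1)),
              format(round(100 * op$recall, 1))))
  cat("top features:\n")
  print(head(x$importance, 5), row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' @param ev `shb_evaluation`.
#' @param dir output directory; writes `evaluation.json`, `sweep.tsv`,
#'   `roc.tsv` and `importance.tsv`.
#' @export
write_evaluation <- function(ev, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(ev$sweep, file.path(dir, "sweep.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(ev$roc, file.path(dir, "roc.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(ev$importance, file.path(dir, "importance.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(auc = ev$auc, threshold = ev$threshold,
         operating_point = ev$operating_point,
         importance = ev$importance),
    file.path(dir, "evaluation.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
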