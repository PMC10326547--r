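# Evaluation harness: confusion counts with senescent as the positive
# class, the four headline metrics (accuracy, precision, recall, F1), the
# ROC curve with trapezoidal AUC, and mean +/- SD summaries over repeated
# training runs.

#' Confusion counts (senescent = positive class)
#'
#' TP: correctly predicted senescent; TN: correctly predicted control;
#' FP: control predicted senescent; FN: senescent predicted control.
#'
#' @param pred,truth Equal-length character vectors of labels.
#' @return List of class `confusion_counts` (`TP`, `TN`, `FP`, `FN`).
#' @export
confusion_counts <- function(pred, truth) {
  pred <- toupper(as.character(pred)); truth <- toupper(as.character(truth))
  if (length(pred) != length(truth) || length(pred) == 0)
    stop("confusion_counts: pred and truth must be equal-length, non-empty")
  structure(list(
    TP = sum(pred == "SENESCENT" & truth == "SENESCENT"),
    TN = sum(pred == "CONTROL" & truth == "CONTROL"),
    FP = sum(pred == "SENESCENT" & truth == "CONTROL"),
    FN = sum(pred == "CONTROL" & truth == "SENESCENT")),
    class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' accuracy = (TP+TN)/(TP+TN+FP+FN); precision = TP/(TP+FP);
#' recall = TP/(TP+FN); F1 = 2TP/(2TP+FP+FN). A metric whose denominator
#' is zero is reported as `NA` rather than 0, so degenerate predictions do
#' not silently inflate summaries.
#'
#' @param c A `confusion_counts` (or list with TP/TN/FP/FN).
#' @return List of class `metric_set` (`accuracy`, `precision`, `recall`,
#'   `f1`), fractions in \[0, 1\].
#' @export
compute_metrics <- function(c) {
  total <- c$TP + c$TN + c$FP + c$FN
  if (total == 0) stop("compute_metrics: no evaluated images")
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(accuracy = (c$TP + c$TN) / total,
                 precision = safe(c$TP, c$TP + c$FP),
                 recall = safe(c$TP, c$TP + c$FN),
                 f1 = safe(2 * c$TP, 2 * c$TP + c$FP + c$FN)),
            class = "metric_set")
}

#' ROC curve and trapezoidal AUC
#'
#' Sweeps the decision threshold over the unique predicted probabilities
#' (plus sentinels), computing TPR/FPR from the confusion counts at each
#' threshold; the AUC is the trapezoidal area under the resulting curve.
#' Both classes must be present in `truth`, otherwise the AUC is
#' undefined.
#'
#' @param probs Numeric vector of senescence probabilities.
#' @param truth Character vector of true labels.
#' @return List of class `roc_curve` with `points` (data frame
#'   `threshold`, `fpr`, `tpr`, sorted by increasing FPR, endpoints (0,0)
#'   and (1,1) included) and `auc`.
#' @export
roc_curve <- function(probs, truth) {
  truth <- toupper(as.character(truth))
  pos <- truth == "SENESCENT"
  if (!any(pos) || all(pos))
    stop("roc_curve: both classes must be present (AUC undefined otherwise)")
  thresholds <- c(Inf, sort(unique(probs), decreasing = TRUE), -Inf)
  pts <- t(vapply(thresholds, function(t) {
    pred <- probs >= t
    c(fpr = sum(pred & !pos) / sum(!pos), tpr = sum(pred & pos) / sum(pos))
  }, c(fpr = 0, tpr = 0)))
  df <- data.frame(threshold = thresholds, fpr = pts[, "fpr"],
                   tpr = pts[, "tpr"])
  df <- df[order(df$fpr, df$tpr), ]
  auc <- sum(diff(df$fpr) * (utils::head(df$tpr, -1) + utils::tail(df$tpr, -1)) / 2)
  structure(list(points = df, auc = auc), class = "roc_curve")
}

#' Summary of repeated training runs
#'
#' Per-metric mean and sample standard deviation over the runs (the
#' protocol repeats training nine times to decouple the reported numbers
#' from a single lucky initialization), plus the maximum AUC across runs.
#'
#' @param metric_sets List of `metric_set`s, one per run.
#' @param aucs Numeric vector of per-run AUCs (optional).
#' @return List of class `run_summary` with `mean`, `sd` (named vectors
#'   over accuracy/precision/recall/f1), `max_auc`, `n_runs` and the raw
#'   per-run table `runs`.
#' @export
summarize_runs <- function(metric_sets, aucs = numeric()) {
  if (length(metric_sets) < 1) stop("summarize_runs: no runs")
  tab <- do.call(rbind, lapply(metric_sets, function(m) {
    data.frame(accuracy = m$accuracy, precision = m$precision,
               recall = m$recall, f1 = m$f1)
  }))
  if (length(aucs) == nrow(tab)) tab$auc <- aucs
  means <- vapply(tab[c("accuracy", "precision", "recall", "f1")],
                  mean, 0, na.rm = TRUE)
  sds <- vapply(tab[c("accuracy", "precision", "recall", "f1")], function(x) {
    if (length(x) > 1) stats::sd(x, na.rm = TRUE) else 0
  }, 0)
  structure(list(mean = means, sd = sds,
                 max_auc = if (length(aucs)) max(aucs) else NA_real_,
                 n_runs = nrow(tab), runs = tab),
            class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf("<run_summary> %d runs\n", x$n_runs))
  for (m in names(x$mean))
    cat(sprintf("  %-9s %5.1f%% +/- %.1f%%\n", m,
                100 * x$mean[[m]], 100 * x$sd[[m]]))
  if (!is.na(x$max_auc)) cat(sprintf("  max AUC   %.3f\n", x$max_auc))
  invisible(x)
}

#' Evaluate predicted labels (and optionally probabilities) on a bundle
#'
#' @param pred Character vector of predicted labels.
#' @param ds A [dataset_bundle()] supplying the ground truth.
#' @param probs Optional senescence probabilities for ROC/AUC.
#' @return List with `counts`, `metrics` and (when `probs` given) `roc`.
#' @export
evaluate_predictions <- function(pred, ds, probs = NULL) {
  truth <- bundle_labels(ds)
  counts <- confusion_counts(pred, truth)
  out <- list(counts = counts, metrics = compute_metrics(counts))
  if (!is.null(probs)) out$roc <- roc_curve(probs, truth)
  out
}
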