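#' Construct a confusion matrix
#'
#' @param tp,fp,fn,tn Non-negative integer counts (true/false
#'   positives/negatives against the gold standard).
#' @return A list of class `confusion` with fields `tp`, `fp`, `fn`, `tn`.
#' @examples
#' confusion_matrix(tp = 495, fp = 37, fn = 311, tn = 1427)
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts %% 1 != 0)) {
    abort("confusion counts must be non-negative integers")
  }
  if (sum(counts) == 0) abort("confusion matrix is all zero")
  structure(as.list(counts), class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(c("pred +", "pred -"), c("actual +", "actual -")))
  print(m)
  invisible(x)
}

#' Tally a confusion matrix from calls and labels
#'
#' @param calls Logical (or 0/1) predicted calls.
#' @param labels Logical (or "positive"/"negative") gold-standard labels.
#' @return A [confusion_matrix()].
#' @export
confusion_counts <- function(calls, labels) {
  calls <- as.logical(calls)
  if (is.character(labels) || is.factor(labels)) labels <- labels == "positive"
  labels <- as.logical(labels)
  keep <- !is.na(calls) & !is.na(labels)
  calls <- calls[keep]; labels <- labels[keep]
  confusion_matrix(
    tp = sum(calls & labels), fp = sum(calls & !labels),
    fn = sum(!calls & labels), tn = sum(!calls & !labels)
  )
}

#' Standard performance metrics from a confusion matrix
#'
#' Computes accuracy `(TP+TN)/total`, sensitivity `TP/(TP+FN)`,
#' specificity `TN/(FP+TN)`, false positive rate `FP/(FP+TN)` and false
#' discovery rate `FP/(TP+FP)` at full precision (proportions in
#' \[0, 1\]). A metric whose denominator is zero is reported as `NA`
#' (undefined), never as 0. Use [report_percent()] to format as
#' percentages rounded to two decimals.
#'
#' @param cm A [confusion_matrix()].
#' @return A one-row tibble with the five metrics plus the counts.
#' @examples
#' confusion_metrics(confusion_matrix(tp = 338, fp = 63, fn = 468, tn = 1401))
#' @export
confusion_metrics <- function(cm) {
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  tibble(
    tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn,
    accuracy = safe_div(cm$tp + cm$tn, cm$tp + cm$fp + cm$fn + cm$tn),
    sensitivity = safe_div(cm$tp, cm$tp + cm$fn),
    specificity = safe_div(cm$tn, cm$fp + cm$tn),
    fpr = safe_div(cm$fp, cm$fp + cm$tn),
    fdr = safe_div(cm$fp, cm$tp + cm$fp)
  )
}

#' Format proportions as percentages rounded half-up
#'
#' Reporting-layer rounding only: internal metric values stay at full
#' precision.
#'
#' @param x Numeric proportions in \[0, 1\].
#' @param digits Decimal places; default 2.
#' @return Numeric percentages (e.g. 0.84669... -> 84.67).
#' @export
report_percent <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * 100 * scale + 0.5) / scale
}

#' Build a ROC curve by threshold sweep
#'
#' Sweeps the classification threshold over the unique score values plus
#' infinite sentinels; at each threshold a protein is called positive when
#' its score is strictly greater. Tied scores therefore move between the
#' called and not-called sets as a block. The area under the curve is
#' computed by the trapezoid rule and equals the Mann-Whitney
#' probability that a random positive outscores a random negative, ties
#' counted half.
#'
#' @param scores Numeric per-protein scores (higher = more mitochondrial).
#' @param labels Gold-standard labels: logical, or
#'   `"positive"`/`"negative"`.
#' @return A tibble of class `mito_roc` with columns `threshold`, `fpr`,
#'   `tpr`, attributes `auc`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels) {
  if (is.character(labels) || is.factor(labels)) labels <- labels == "positive"
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) abort("both classes must be present")
  thresholds <- c(-Inf, sort(unique(scores)))
  tpr <- vapply(thresholds, function(t) sum(scores > t & labels) / n_pos, numeric(1))
  fpr <- vapply(thresholds, function(t) sum(scores > t & !labels) / n_neg, numeric(1))
  out <- tibble(threshold = thresholds, fpr = fpr, tpr = tpr)
  # trapezoid AUC over the curve traced from (0,0) to (1,1)
  ord <- order(out$fpr, out$tpr)
  xs <- out$fpr[ord]; ys <- out$tpr[ord]
  auc <- sum(diff(xs) * (head(ys, -1) + ys[-1]) / 2)
  structure(out, auc = auc, n_pos = n_pos, n_neg = n_neg,
            class = c("mito_roc", class(out)))
}

#' Area under a ROC curve
#'
#' @param roc A [roc_curve()] object.
#' @return The trapezoid AUC in \[0, 1\].
#' @export
roc_auc <- function(roc) attr(roc, "auc")

#' @export
print.mito_roc <- function(x, ...) {
  cat(sprintf("<ROC curve> %d points, AUC = %.4f (%d positives, %d negatives)\n",
              nrow(x), attr(x, "auc"), attr(x, "n_pos"), attr(x, "n_neg")))
  NextMethod()
}

#' Select an operating threshold on a ROC curve
#'
#' Criteria: `"max_accuracy"` maximises `(TPR * AP + (1 - FPR) * AN) /
#' (AP + AN)`; `"max_youden"` maximises `TPR - FPR`; `"fpr_cap"` returns
#' the smallest threshold whose FPR does not exceed `fpr_cap`. For the
#' maximising criteria, ties break toward the larger (more conservative)
#' threshold.
#'
#' @param roc A [roc_curve()] object.
#' @param criterion One of `"max_accuracy"`, `"max_youden"`, `"fpr_cap"`.
#' @param fpr_cap Required when `criterion = "fpr_cap"`.
#' @return The selected threshold (a score value, possibly `-Inf`).
#' @export
select_threshold <- function(roc, criterion = c("max_accuracy", "max_youden", "fpr_cap"),
                             fpr_cap = NULL) {
  criterion <- match.arg(criterion)
  if (nrow(roc) == 0) abort("empty ROC curve")
  n_pos <- attr(roc, "n_pos"); n_neg <- attr(roc, "n_neg")
  if (criterion == "fpr_cap") {
    if (is.null(fpr_cap)) abort("fpr_cap criterion needs a cap value")
    ok <- roc$fpr <= fpr_cap
    if (!any(ok)) abort("no threshold satisfies the FPR cap")
    return(min(roc$threshold[ok]))
  }
  objective <- switch(
    criterion,
    max_accuracy = (roc$tpr * n_pos + (1 - roc$fpr) * n_neg) / (n_pos + n_neg),
    max_youden = roc$tpr - roc$fpr
  )
  best <- which(objective == max(objective))
  max(roc$threshold[best])
}

#' Stratified k-fold cross-validation of the integration
#'
#' Splits the labelled proteins into `k` label-stratified folds
#' (deterministic given `seed`), re-estimates the per-predictor likelihood
#' ratios on each training split, scores and classifies the held-out
#' proteins, and pools the held-out predictions into one confusion matrix.
#'
#' @param features Feature tibble.
#' @param catalog Catalog tibble (only labelled proteins enter CV).
#' @param k Number of folds, `>= 2`.
#' @param alpha Pseudocount for [estimate_likelihood_ratios()].
#' @param threshold log10-LR classification threshold.
#' @param seed Integer seed for fold assignment.
#' @param missing_policy Passed to [integrate_evidence()].
#' @return An object of class `mito_cv`: list with `metrics` (pooled
#'   tibble), `confusion`, `scores` (held-out per-protein scores), and the
#'   settings used.
#' @export
kfold_cv <- function(features, catalog, k = 10, alpha = 1, threshold = 1.37,
                     seed = 1L, missing_policy = "skip") {
  if (k < 2) abort("k must be >= 2")
  features <- validate_features(features)
  catalog <- validate_catalog(catalog)
  labelled <- catalog[catalog$label %in% c("positive", "negative"), ]
  feats <- features[match(labelled$protein_id, features$protein_id), , drop = FALSE]
  if (anyNA(feats$protein_id)) abort("features do not cover all labelled proteins")
  folds <- stratified_folds(labelled$label, k, seed)
  held <- vector("list", k)
  for (f in seq_len(k)) {
    train_cat <- labelled[folds != f, , drop = FALSE]
    train_feat <- feats[folds != f, , drop = FALSE]
    test_feat <- feats[folds == f, , drop = FALSE]
    lr <- estimate_likelihood_ratios(train_feat, train_cat, alpha = alpha)
    sc <- integrate_evidence(test_feat, lr, missing_policy = missing_policy)
    sc <- classify_proteins(sc, threshold)
    sc$label <- labelled$label[folds == f]
    sc$fold <- f
    held[[f]] <- sc
  }
  scores <- bind_rows(held)
  cm <- confusion_counts(scores$call, scores$label)
  structure(
    list(metrics = confusion_metrics(cm), confusion = cm, scores = scores,
         k = k, alpha = alpha, threshold = threshold, seed = seed),
    class = "mito_cv"
  )
}

#' @export
print.mito_cv <- function(x, ...) {
  cat(sprintf("<%d-fold cross-validation> threshold %.2f, alpha %.2f\n",
              x$k, x$threshold, x$alpha))
  cat(sprintf("  accuracy %.2f%%  sensitivity %.2f%%  specificity %.2f%%\n",
              100 * x$metrics$accuracy, 100 * x$metrics$sensitivity,
              100 * x$metrics$specificity))
  invisible(x)
}
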