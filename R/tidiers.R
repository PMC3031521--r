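#' Tidy a likelihood-ratio table
#'
#' @param x A [estimate_likelihood_ratios()] table.
#' @param ... Unused.
#' @return A tibble with one row per predictor: counts, smoothed call
#'   probabilities, `L1`, `L0` and their log10s.
#' @method tidy mito_lr_table
#' @export
tidy.mito_lr_table <- function(x, ...) {
  out <- as_tibble(x)
  out$log10_L1 <- log10(out$L1)
  out$log10_L0 <- log10(out$L0)
  out
}

#' Summarise a likelihood-ratio table
#'
#' @param x A [estimate_likelihood_ratios()] table.
#' @param ... Unused.
#' @return One-row tibble: number of predictors, pseudocount, and the
#'   attainable log10-LR score range (every predictor at its most/least
#'   favourable call).
#' @method glance mito_lr_table
#' @export
glance.mito_lr_table <- function(x, ...) {
  tibble(
    n_predictors = nrow(x),
    alpha = attr(x, "alpha"),
    max_log_lr = sum(pmax(log10(x$L1), log10(x$L0))),
    min_log_lr = sum(pmin(log10(x$L1), log10(x$L0)))
  )
}

#' Tidy a ROC curve
#'
#' @param x A [roc_curve()] object.
#' @param ... Unused.
#' @return The threshold/FPR/TPR points as a plain tibble.
#' @method tidy mito_roc
#' @export
tidy.mito_roc <- function(x, ...) as_tibble(x)

#' Summarise a ROC curve
#'
#' @param x A [roc_curve()] object.
#' @param ... Unused.
#' @return One-row tibble with `auc`, `n_pos`, `n_neg`, `n_points`.
#' @method glance mito_roc
#' @export
glance.mito_roc <- function(x, ...) {
  tibble(auc = attr(x, "auc"), n_pos = attr(x, "n_pos"),
         n_neg = attr(x, "n_neg"), n_points = nrow(x))
}

#' Tidy a coexpression classifier fit
#'
#' @param x A [train_coexpression_classifier()] fit.
#' @param ... Unused.
#' @return Tibble of per-dataset variable importance from the fitted tree
#'   (datasets the tree never split on get importance 0).
#' @method tidy coexpression_fit
#' @export
tidy.coexpression_fit <- function(x, ...) {
  imp <- x$tree$variable.importance
  out <- tibble(dataset_id = x$dataset_ids, importance = 0)
  if (!is.null(imp)) {
    hit <- match(names(imp), out$dataset_id)
    out$importance[hit[!is.na(hit)]] <- imp[!is.na(hit)]
  }
  arrange(out, dplyr::desc(.data$importance))
}

#' Summarise a coexpression classifier fit
#'
#' @param x A [train_coexpression_classifier()] fit.
#' @param ... Unused.
#' @return One-row tibble with the cross-validated metrics and settings.
#' @method glance coexpression_fit
#' @export
glance.coexpression_fit <- function(x, ...) {
  bind_cols(
    x$cv_metrics,
    tibble(cv_folds = x$params$cv_folds,
           confidence_factor = x$params$confidence_factor,
           min_leaf = x$params$min_leaf)
  )
}

#' Summarise a cross-validation run
#'
#' @param x A [kfold_cv()] object.
#' @param ... Unused.
#' @return One-row tibble: pooled metrics plus `k`, `alpha`, `threshold`.
#' @method glance mito_cv
#' @export
glance.mito_cv <- function(x, ...) {
  bind_cols(x$metrics, tibble(k = x$k, alpha = x$alpha, threshold = x$threshold))
}
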