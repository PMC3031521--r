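#' N50 coexpression neighbour counts
#'
#' For each gene and each expression dataset, counts how many gold-standard
#' mitochondrial genes appear among the gene's `k` closest neighbours by
#' Euclidean distance over the dataset's samples (the N50 metric, `k = 50`
#' by default). The gene itself is excluded from its own neighbour list;
#' distance ties are broken by ascending gene id so the counts are
#' deterministic. Genes absent from a dataset get `NA` in that dataset's
#' column.
#'
#' @param datasets Named list of expression tibbles (`gene_id` + sample
#'   columns), as returned by [generate_expression()] or [read_expression()].
#' @param gsp_ids Character vector of gold-standard positive gene ids.
#' @param k Neighbourhood size; every dataset must contain at least `k + 1`
#'   genes.
#' @return A tibble with `gene_id` (the union of genes over datasets) and
#'   one integer count column per dataset.
#' @export
n50_counts <- function(datasets, gsp_ids, k = 50) {
  if (k < 1) abort("k must be >= 1")
  if (is.null(names(datasets)) || any(names(datasets) == "")) {
    names(datasets) <- sprintf("D%02d", seq_along(datasets))
  }
  all_genes <- sort(unique(unlist(lapply(datasets, function(d) d$gene_id))))
  out <- tibble(gene_id = all_genes)
  for (nm in names(datasets)) {
    d <- datasets[[nm]]
    genes <- d$gene_id
    ng <- length(genes)
    if (ng < k + 1) {
      abort(paste0("dataset ", nm, " has ", ng, " genes; need at least k+1 = ", k + 1))
    }
    x <- as.matrix(d[setdiff(names(d), "gene_id")])
    dm <- as.matrix(dist(x))
    is_gsp <- genes %in% gsp_ids
    # tie-break: order by (distance, gene_id ascending)
    id_rank <- rank(genes, ties.method = "first")
    counts <- vapply(seq_len(ng), function(i) {
      di <- dm[i, ]
      di[i] <- Inf               # exclude the query gene itself
      nb <- order(di, id_rank)[seq_len(k)]
      sum(is_gsp[nb])
    }, integer(1))
    col <- rep(NA_integer_, length(all_genes))
    col[match(genes, all_genes)] <- counts
    out[[nm]] <- col
  }
  out
}

#' Decision-tree training parameters for the coexpression classifier
#'
#' The classifier is an axis-aligned decision tree over the per-dataset N50
#' count vectors. `confidence_factor` is a pruning-strength knob on the
#' C4.5 scale (smaller prunes harder); internally it maps to the rpart
#' complexity parameter as `cp = 0.01 * 0.25 / confidence_factor`, so the
#' conventional 0.25 corresponds to rpart's default `cp = 0.01`.
#'
#' @param confidence_factor Pruning knob in (0, 1); default 0.25.
#' @param min_leaf Minimum observations per leaf; default 2.
#' @param cv_folds Cross-validation folds; default 10.
#' @param seed Integer seed for fold assignment.
#' @return A list of class `tree_params`.
#' @export
tree_params <- function(confidence_factor = 0.25, min_leaf = 2L,
                        cv_folds = 10L, seed = 1L) {
  if (confidence_factor <= 0 || confidence_factor >= 1) {
    abort("confidence_factor must lie in (0, 1)")
  }
  if (min_leaf < 1) abort("min_leaf must be >= 1")
  if (cv_folds < 2) abort("cv_folds must be >= 2")
  structure(
    list(confidence_factor = confidence_factor, min_leaf = as.integer(min_leaf),
         cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
    class = "tree_params"
  )
}

# missing N50 counts enter the tree as the sentinel value -1 (counts are
# non-negative, so the sentinel is separable from any real count)
missing_count_sentinel <- -1

count_frame <- function(counts) {
  df <- as.data.frame(counts[setdiff(names(counts), "gene_id")])
  df[is.na(df)] <- missing_count_sentinel
  df
}

rpart_cp <- function(confidence_factor) 0.01 * 0.25 / confidence_factor

# deterministic stratified fold assignment
stratified_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  with_seed(derive_seed(seed, "folds"), {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < k) {
        abort(paste0("class '", cl, "' has fewer members (", length(idx),
                     ") than folds (", k, ")"))
      }
      folds[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
    }
  })
  folds
}

#' Train the N50 coexpression classifier
#'
#' Fits a binary decision tree on the N50 count vectors of the labelled
#' (gold-standard) proteins and estimates its performance by stratified
#' `cv_folds`-fold cross-validation. Missing counts are encoded as the
#' sentinel value -1.
#'
#' @param counts N50 count tibble from [n50_counts()].
#' @param catalog Catalog tibble; only labelled proteins are used.
#' @param params A [tree_params()] object.
#' @return An object of class `coexpression_fit` with elements `tree`
#'   (the rpart fit), `cv_metrics` (pooled cross-validated metrics tibble),
#'   `cv_confusion`, `dataset_ids` and `params`.
#' @export
train_coexpression_classifier <- function(counts, catalog, params = tree_params()) {
  catalog <- validate_catalog(catalog)
  labelled <- catalog[catalog$label %in% c("positive", "negative"), ]
  idx <- match(labelled$protein_id, counts$gene_id)
  if (anyNA(idx)) abort("counts do not cover all labelled proteins")
  if (length(unique(labelled$label)) < 2) {
    abort("training set must contain both classes")
  }
  x <- count_frame(counts[idx, , drop = FALSE])
  y <- factor(labelled$label, levels = c("negative", "positive"))
  df <- cbind(data.frame(.label = y), x)
  control <- rpart::rpart.control(
    minbucket = params$min_leaf,
    cp = rpart_cp(params$confidence_factor),
    xval = 0
  )
  fit <- rpart::rpart(.label ~ ., data = df, method = "class", control = control)

  folds <- stratified_folds(as.character(y), params$cv_folds, params$seed)
  held_out <- factor(rep(NA_character_, nrow(df)), levels = levels(y))
  for (f in seq_len(params$cv_folds)) {
    train <- df[folds != f, , drop = FALSE]
    cv_fit <- rpart::rpart(.label ~ ., data = train, method = "class",
                           control = control)
    held_out[folds == f] <- predict(cv_fit, df[folds == f, , drop = FALSE],
                                    type = "class")
  }
  cm <- confusion_matrix(
    tp = sum(held_out == "positive" & y == "positive"),
    fp = sum(held_out == "positive" & y == "negative"),
    fn = sum(held_out == "negative" & y == "positive"),
    tn = sum(held_out == "negative" & y == "negative")
  )
  structure(
    list(tree = fit,
         cv_metrics = confusion_metrics(cm),
         cv_confusion = cm,
         dataset_ids = setdiff(names(counts), "gene_id"),
         params = params),
    class = "coexpression_fit"
  )
}

#' @export
print.coexpression_fit <- function(x, ...) {
  cat("<coexpression N50 decision tree>\n")
  cat("  datasets:", length(x$dataset_ids), "  CV folds:", x$params$cv_folds, "\n")
  cat(sprintf("  CV accuracy: %.2f%%\n", 100 * x$cv_metrics$accuracy))
  invisible(x)
}

#' Predict mitochondrial calls from N50 counts
#'
#' Scores genes with a trained [train_coexpression_classifier()] tree.
#' Genes whose counts are missing in every dataset get a missing (`NA`)
#' call; partially missing rows use the -1 sentinel the tree was trained
#' with.
#'
#' @param fit A `coexpression_fit`.
#' @param counts N50 count tibble with the same dataset columns the
#'   classifier was trained on.
#' @return A tibble with columns `protein_id` and integer `call`
#'   (1/0/`NA`), usable as one feature-matrix column.
#' @export
predict_coexpression <- function(fit, counts) {
  cols <- setdiff(names(counts), "gene_id")
  if (!setequal(cols, fit$dataset_ids)) {
    abort("count columns do not match the datasets the classifier was trained on")
  }
  counts <- counts[, c("gene_id", fit$dataset_ids)]
  all_missing <- apply(is.na(counts[fit$dataset_ids]), 1, all)
  x <- count_frame(counts)
  pred <- predict(fit$tree, x, type = "class")
  call <- ifelse(pred == "positive", 1L, 0L)
  call[all_missing] <- NA_integer_
  tibble(protein_id = counts$gene_id, call = as.integer(call))
}
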