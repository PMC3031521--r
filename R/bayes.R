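#' Estimate per-predictor likelihood ratios from gold standards
#'
#' For each predictor, tallies calls on gold-standard positives and
#' negatives (proteins with a missing call are excluded from that
#' predictor's tallies) and estimates the class-conditional call
#' probabilities with a pseudocount:
#' `P(call = c | class) = (count + alpha) / (n_class + 2 * alpha)`.
#' The likelihood ratios are `L1 = P(1|pos) / P(1|neg)` and
#' `L0 = P(0|pos) / P(0|neg)`.
#'
#' @param features Feature tibble (see [validate_features()]).
#' @param catalog Catalog tibble with at least one positive and one
#'   negative scored by every predictor.
#' @param alpha Pseudocount, `>= 0`; with `alpha = 0` any zero cell is an
#'   error (infinite ratios are never produced silently). Default 1
#'   (Laplace).
#' @return A tibble of class `mito_lr_table` with the 2x2 tallies, the
#'   smoothed probabilities and `L1`, `L0` per predictor; the pseudocount
#'   is kept in the `alpha` attribute.
#' @examples
#' feats <- tibble::tibble(protein_id = paste0("p", 1:4), s1 = c(1, 1, 0, 0))
#' cat <- protein_catalog(paste0("p", 1:4), c("positive", "positive", "negative", "negative"))
#' estimate_likelihood_ratios(feats, cat, alpha = 1)
#' @export
estimate_likelihood_ratios <- function(features, catalog, alpha = 1) {
  features <- validate_features(features)
  catalog <- validate_catalog(catalog)
  if (alpha < 0) abort("alpha must be >= 0")
  lab <- catalog$label[match(features$protein_id, catalog$protein_id)]
  is_pos <- !is.na(lab) & lab == "positive"
  is_neg <- !is.na(lab) & lab == "negative"
  rows <- lapply(predictor_ids(features), function(pid) {
    call <- features[[pid]]
    n1_pos <- sum(call == 1 & is_pos, na.rm = TRUE)
    n0_pos <- sum(call == 0 & is_pos, na.rm = TRUE)
    n1_neg <- sum(call == 1 & is_neg, na.rm = TRUE)
    n0_neg <- sum(call == 0 & is_neg, na.rm = TRUE)
    n_pos <- n1_pos + n0_pos
    n_neg <- n1_neg + n0_neg
    if (n_pos == 0 || n_neg == 0) {
      abort(paste0("predictor ", pid, " scores no ",
                   if (n_pos == 0) "positive" else "negative", " proteins"))
    }
    if (alpha == 0 && any(c(n1_pos, n0_pos, n1_neg, n0_neg) == 0)) {
      abort(paste0("predictor ", pid,
                   " has a zero count; use alpha > 0 to regularise"))
    }
    p1_pos <- (n1_pos + alpha) / (n_pos + 2 * alpha)
    p1_neg <- (n1_neg + alpha) / (n_neg + 2 * alpha)
    tibble(
      predictor_id = pid,
      n1_pos = n1_pos, n0_pos = n0_pos, n1_neg = n1_neg, n0_neg = n0_neg,
      p1_pos = p1_pos, p1_neg = p1_neg,
      L1 = p1_pos / p1_neg,
      L0 = (1 - p1_pos) / (1 - p1_neg)
    )
  })
  out <- bind_rows(rows)
  structure(out, alpha = alpha, class = c("mito_lr_table", class(out)))
}

#' Prior odds of mitochondrial localization
#'
#' `n_pos / (n_total - n_pos)`: the odds of picking a mitochondrial
#' protein before seeing any predictor evidence. With roughly 1,500
#' mitochondrial proteins among 30,480 nucleus-encoded proteins this is
#' about 1 in 19.
#'
#' @param n_pos Assumed number of positives, `0 < n_pos < n_total`.
#' @param n_total Total number of proteins.
#' @return The prior odds (a positive number).
#' @examples
#' prior_odds(1500, 30480)   # ~ 1/19
#' @export
prior_odds <- function(n_pos, n_total) {
  if (n_pos <= 0 || n_pos >= n_total) abort("need 0 < n_pos < n_total")
  n_pos / (n_total - n_pos)
}

#' Sum per-predictor log likelihood ratios (naive Bayes integration)
#'
#' Under the naive Bayes assumption the posterior odds are the prior odds
#' times the product of per-predictor likelihood ratios, so on the log10
#' scale each protein's integrated score is the sum over predictors of
#' `log10(L1)` when the call is 1 and `log10(L0)` when it is 0. Missing
#' calls are skipped by default (absence of evidence contributes nothing);
#' `missing_policy = "as_absent"` treats them as 0-calls instead.
#'
#' @param features Feature tibble; its predictors must all appear in `lr`.
#' @param lr A [estimate_likelihood_ratios()] table.
#' @param missing_policy `"skip"` (default) or `"as_absent"`.
#' @param oprior Optional prior odds; when given, posterior odds
#'   `oprior * 10^log_lr` are included.
#' @return A tibble of class `mito_scores` with `protein_id`, `log_lr`,
#'   `n_used` (predictors contributing) and optionally `posterior_odds`.
#' @export
integrate_evidence <- function(features, lr, missing_policy = c("skip", "as_absent"),
                               oprior = NULL) {
  features <- validate_features(features)
  missing_policy <- match.arg(missing_policy)
  pids <- predictor_ids(features)
  unknown <- setdiff(pids, lr$predictor_id)
  if (length(unknown) > 0) {
    abort(paste0("predictors not in likelihood table: ", paste(unknown, collapse = ", ")))
  }
  log_lr <- numeric(nrow(features))
  n_used <- integer(nrow(features))
  for (pid in pids) {
    row <- lr[lr$predictor_id == pid, ]
    call <- features[[pid]]
    if (missing_policy == "as_absent") call[is.na(call)] <- 0L
    contrib <- ifelse(is.na(call), 0, ifelse(call == 1, log10(row$L1), log10(row$L0)))
    log_lr <- log_lr + contrib
    n_used <- n_used + !is.na(call)
  }
  out <- tibble(protein_id = features$protein_id, log_lr = log_lr, n_used = n_used)
  if (!is.null(oprior)) out$posterior_odds <- oprior * 10^out$log_lr
  structure(out, class = c("mito_scores", class(out)))
}

#' Threshold integrated scores into mitochondrial calls
#'
#' A protein is called mitochondrial when its summed log10 likelihood
#' ratio strictly exceeds the threshold (the published operating point
#' uses `threshold = 1.37`; scores exactly at the threshold are negative).
#'
#' @param scores A [integrate_evidence()] tibble.
#' @param threshold Finite log10-LR threshold.
#' @return `scores` with a logical `call` column added.
#' @export
classify_proteins <- function(scores, threshold) {
  if (!is.finite(threshold)) abort("threshold must be finite")
  scores$call <- scores$log_lr > threshold
  scores
}

#' Merge a predictor group by record-count voting (indirect merge)
#'
#' Collapses a set of predictors into one binary feature: the merged call
#' is 1 when at least `record_threshold` of the group's predictors call
#' the protein positive (missing calls never count as records). The
#' published grouping uses threshold 4 for the nine targeting-signal
#' predictors and 2 for the four phylogenetic predictors.
#'
#' @param features Feature tibble.
#' @param group Character vector of predictor ids to merge (non-empty,
#'   all present in `features`).
#' @param record_threshold Votes required, `1 <= record_threshold <= |group|`.
#' @return A tibble with `protein_id` and the merged integer `call`.
#' @export
merge_group_indirect <- function(features, group, record_threshold) {
  features <- validate_features(features)
  if (length(group) == 0) abort("group must be non-empty")
  missing <- setdiff(group, predictor_ids(features))
  if (length(missing) > 0) {
    abort(paste0("group predictors not in features: ", paste(missing, collapse = ", ")))
  }
  if (record_threshold > length(group) || record_threshold < 1) {
    abort("record_threshold must lie in [1, |group|]")
  }
  m <- as.matrix(features[group])
  records <- rowSums(m == 1, na.rm = TRUE)
  tibble(protein_id = features$protein_id,
         call = as.integer(records >= record_threshold))
}

#' Merge a predictor group as a union (direct merge)
#'
#' The direct-merge strategy: the merged call is the logical OR of the
#' group's calls, i.e. [merge_group_indirect()] with `record_threshold = 1`.
#'
#' @inheritParams merge_group_indirect
#' @return A tibble with `protein_id` and the merged integer `call`.
#' @export
merge_group_direct <- function(features, group) {
  merge_group_indirect(features, group, record_threshold = 1)
}

#' Assemble the core mitochondrial protein set
#'
#' Joins the integrated predictions with experimentally verified
#' mitochondrial proteins and removes known non-mitochondrial proteins:
#' `(integrated_calls | experimental_positives) \ known_negatives`.
#'
#' @param integrated_calls Character vector (or tibble with `protein_id`)
#'   of proteins called by the integrated classifier.
#' @param experimental_positives Character vector of experimentally
#'   verified mitochondrial proteins.
#' @param known_negatives Character vector of proteins to exclude.
#' @return A sorted, de-duplicated character vector of protein ids.
#' @export
assemble_core_set <- function(integrated_calls, experimental_positives = character(),
                              known_negatives = character()) {
  as_ids <- function(x) {
    if (is.data.frame(x)) x <- x$protein_id
    unique(as.character(x))
  }
  sort(setdiff(union(as_ids(integrated_calls), as_ids(experimental_positives)),
               as_ids(known_negatives)))
}
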