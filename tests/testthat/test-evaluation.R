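test_that("confusion metrics reproduce the published per-tool arithmetic", {
  # TargetP row: reconstructed counts at AP = 806, AN = 1464
  m <- confusion_metrics(confusion_matrix(tp = 338, fp = 63, fn = 468, tn = 1401))
  expect_equal(report_percent(m$accuracy), 76.61)
  expect_equal(report_percent(m$fdr), 15.71)
  # integrated-set row
  m2 <- confusion_metrics(confusion_matrix(tp = 495, fp = 37, fn = 311, tn = 1427))
  expect_equal(report_percent(m2$accuracy), 84.67)
  expect_equal(report_percent(m2$specificity), 97.47)
  expect_equal(report_percent(m2$fdr), 6.95)
})

test_that("zero-denominator metrics are undefined, not zero", {
  m <- confusion_metrics(confusion_matrix(tp = 0, fp = 0, fn = 5, tn = 5))
  expect_true(is.na(m$fdr))
  expect_equal(m$accuracy, 0.5)
  expect_error(confusion_matrix(0, 0, 0, 0), "all zero")
})

test_that("metric identities hold for random confusion matrices", {
  withr::local_seed(40)
  for (i in 1:20) {
    cm <- confusion_matrix(sample(1:50, 1), sample(1:50, 1),
                           sample(1:50, 1), sample(1:50, 1))
    m <- confusion_metrics(cm)
    ap <- cm$tp + cm$fn; an <- cm$fp + cm$tn
    expect_equal(m$accuracy, (m$sensitivity * ap + m$specificity * an) / (ap + an))
    expect_equal(m$fpr + m$specificity, 1)
  }
})

test_that("ROC handles separation, ties, and the enumerated 4-point example", {
  sep <- roc_curve(c(5, 4, 1, 0), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(roc_auc(sep), 1)
  flat <- roc_curve(rep(2, 6), rep(c(TRUE, FALSE), 3))
  expect_equal(roc_auc(flat), 0.5)
  ex <- roc_curve(c(3, 2, 1, 0), c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(roc_auc(ex), 2 / 3)
  expect_error(roc_curve(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("ROC AUC equals the brute-force Mann-Whitney statistic", {
  withr::local_seed(41)
  for (trial in 1:10) {
    n <- sample(20:120, 1)
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c(TRUE, FALSE)
    # mix of continuous and heavily tied score regimes
    scores <- if (trial %% 2) rnorm(n) else sample(0:4, n, replace = TRUE) +
      ifelse(labels, 0.4, 0)
    roc <- roc_curve(scores, labels)
    expect_equal(roc_auc(roc), oracle_auc(scores, labels))
    # monotonicity: TPR and FPR non-increasing in threshold
    expect_true(all(diff(roc$tpr) <= 1e-12))
    expect_true(all(diff(roc$fpr) <= 1e-12))
  }
})

test_that("threshold selection honours criterion and conservative tie-break", {
  roc <- roc_curve(c(5, 4, 1, 0), c(TRUE, TRUE, FALSE, FALSE))
  # perfect separation: the largest threshold below the positive block wins
  expect_equal(select_threshold(roc, "max_accuracy"), 1)
  expect_equal(select_threshold(roc, "max_youden"), 1)
  # tie-break toward the conservative (larger) threshold when accuracies tie
  roc_tie <- roc_curve(c(1, 1), c(TRUE, FALSE))
  expect_equal(select_threshold(roc_tie, "max_accuracy"), 1)
  scores <- c(3, 2.5, 2, 1, 0.5, 0)
  labels <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  roc2 <- roc_curve(scores, labels)
  capped <- select_threshold(roc2, "fpr_cap", fpr_cap = 1 / 3)
  expect_equal(capped, min(roc2$threshold[roc2$fpr <= 1 / 3]))
  expect_error(select_threshold(roc2, "fpr_cap", fpr_cap = -1), "cap")
})

test_that("cross-validation is perfect on separable features and chance on permuted labels", {
  catl <- toy_catalog(40, 40)
  feats <- tibble::tibble(protein_id = catl$protein_id,
                          s1 = as.integer(catl$label == "positive"))
  cv <- kfold_cv(feats, catl, k = 5, alpha = 1, threshold = 0, seed = 1)
  expect_equal(cv$metrics$accuracy, 1)

  withr::local_seed(42)
  n_pos <- 700; n_neg <- 1300
  cat2 <- protein_catalog(sprintf("p%04d", 1:2000),
                          sample(rep(c("positive", "negative"), c(n_pos, n_neg))))
  feats2 <- tibble::tibble(protein_id = cat2$protein_id)
  for (j in 1:5) feats2[[paste0("s", j)]] <- sample(0:1, 2000, replace = TRUE)
  # with uninformative predictors the summed log-LR stays near zero, so the
  # conservative published threshold sends essentially everything negative
  cv2 <- kfold_cv(feats2, cat2, k = 5, alpha = 1, threshold = 1.37, seed = 2)
  expect_lt(abs(cv2$metrics$accuracy - n_neg / 2000), 0.05)
})

test_that("CV accuracy at reference operating points tracks full-data accuracy", {
  # gold-standard-scale catalog, full 14-predictor ensemble; 10-fold CV should sit
  # in a narrow band around training-set accuracy
  accs <- vapply(1:5, function(s) {
    cfg <- synth_config(seed = s)
    catl <- generate_gold_standard(cfg)
    feats <- generate_predictor_calls(catl, reference_profiles(), seed = s)
    lr <- estimate_likelihood_ratios(feats, catl, alpha = 1)
    sc <- integrate_evidence(feats, lr)
    roc <- roc_curve(sc$log_lr, catl$label)
    thr <- select_threshold(roc, "max_accuracy")
    full <- confusion_metrics(confusion_counts(sc$log_lr > thr, catl$label))$accuracy
    cv <- kfold_cv(feats, catl, k = 10, alpha = 1, threshold = thr, seed = s)
    cv$metrics$accuracy - full
  }, numeric(1))
  expect_true(all(abs(accs) < 0.05))
})

test_that("stratification rejects classes smaller than the fold count", {
  catl <- toy_catalog(3, 40)
  feats <- tibble::tibble(protein_id = catl$protein_id, s1 = 0L)
  expect_error(kfold_cv(feats, catl, k = 5, threshold = 0), "fewer members")
})
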