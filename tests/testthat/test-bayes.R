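make_counts_features <- function() {
  # 10 positives of which 8 call=1; 10 negatives of which 2 call=1
  catl <- toy_catalog(10, 10)
  feats <- tibble::tibble(
    protein_id = catl$protein_id,
    s1 = c(rep(1L, 8), rep(0L, 2), rep(1L, 2), rep(0L, 8))
  )
  list(catalog = catl, features = feats)
}

test_that("likelihood ratios match direct frequency counts", {
  d <- make_counts_features()
  lr0 <- estimate_likelihood_ratios(d$features, d$catalog, alpha = 0)
  expect_equal(lr0$L1, 0.8 / 0.2)
  expect_equal(lr0$L0, 0.2 / 0.8)
  lr1 <- estimate_likelihood_ratios(d$features, d$catalog, alpha = 1)
  expect_equal(lr1$L1, (9 / 12) / (3 / 12))
})

test_that("uninformative predictors give unit ratios and zero contribution", {
  catl <- toy_catalog(4, 4)
  feats <- tibble::tibble(protein_id = catl$protein_id,
                          s1 = rep(c(1L, 0L), 4))
  lr <- estimate_likelihood_ratios(feats, catl, alpha = 0)
  expect_equal(lr$L1, 1)
  expect_equal(lr$L0, 1)
  sc <- integrate_evidence(feats, lr)
  expect_equal(sc$log_lr, rep(0, 8))
})

test_that("zero-count cells require a pseudocount", {
  catl <- toy_catalog(3, 3)
  feats <- tibble::tibble(protein_id = catl$protein_id,
                          s1 = c(1L, 1L, 1L, 0L, 0L, 0L))
  expect_error(estimate_likelihood_ratios(feats, catl, alpha = 0), "alpha")
  lr <- estimate_likelihood_ratios(feats, catl, alpha = 1)
  expect_true(all(is.finite(c(lr$L1, lr$L0))))
})

test_that("prior odds arithmetic matches the published scale", {
  expect_equal(prior_odds(1500, 30480), 1500 / 28980)
  expect_equal(round(1 / prior_odds(1500, 30480)), 19)
  expect_equal(prior_odds(10, 20), 1)
  expect_equal(prior_odds(1, 21), 0.05)
  expect_error(prior_odds(0, 10), "n_pos")
  expect_error(prior_odds(10, 10), "n_pos")
})

test_that("integration sums log10 ratios and honours the missing policy", {
  catl <- toy_catalog(2, 2)
  lr <- structure(
    tibble::tibble(predictor_id = c("a", "b"), L1 = c(4, 2), L0 = c(0.5, 0.25)),
    class = c("mito_lr_table", "tbl_df", "tbl", "data.frame")
  )
  feats <- tibble::tibble(protein_id = "p", a = 1L, b = 1L)
  sc <- integrate_evidence(feats, lr)
  expect_equal(sc$log_lr, log10(8))

  feats_na <- tibble::tibble(protein_id = "p", a = 1L, b = NA_integer_)
  expect_equal(integrate_evidence(feats_na, lr)$log_lr, log10(4))
  expect_equal(integrate_evidence(feats_na, lr)$n_used, 1L)
  expect_equal(integrate_evidence(feats_na, lr, "as_absent")$log_lr,
               log10(4) + log10(0.25))

  # no predictors -> zero score, posterior equals prior
  none <- tibble::tibble(protein_id = "p", a = NA_integer_)
  sc0 <- integrate_evidence(none, lr, oprior = 0.05)
  expect_equal(sc0$log_lr, 0)
  expect_equal(sc0$posterior_odds, 0.05)

  expect_error(integrate_evidence(tibble::tibble(protein_id = "p", zz = 1L), lr),
               "zz")
})

test_that("log-LR is additive over predictor subsets", {
  withr::local_seed(30)
  cfg <- synth_config(n_pos = 50, n_neg = 80, seed = 31)
  catl <- generate_gold_standard(cfg)
  feats <- generate_predictor_calls(catl, reference_profiles(), seed = 31)
  lr <- estimate_likelihood_ratios(feats, catl, alpha = 1)
  a_cols <- c("protein_id", paste0("s", 1:7))
  b_cols <- c("protein_id", paste0("s", 8:14))
  sum_ab <- integrate_evidence(feats[a_cols], lr)$log_lr +
    integrate_evidence(feats[b_cols], lr)$log_lr
  expect_equal(sum_ab, integrate_evidence(feats, lr)$log_lr)
})

test_that("classification is strict at the threshold and monotone in it", {
  sc <- tibble::tibble(protein_id = c("a", "b", "c"),
                       log_lr = c(1.40, 1.37, -5), n_used = 14L)
  called <- classify_proteins(sc, 1.37)
  expect_equal(called$call, c(TRUE, FALSE, FALSE))
  expect_true(all(classify_proteins(sc, -100)$call))
  lo <- classify_proteins(sc, 0.5)$call
  hi <- classify_proteins(sc, 1.5)$call
  expect_true(all(hi <= lo))
})

test_that("group merging implements record-count voting with OR/AND limits", {
  feats <- tibble::tibble(
    protein_id = c("p1", "p2", "p3"),
    s1 = c(1L, 1L, 0L), s2 = c(1L, 0L, 0L), s3 = c(1L, NA, 0L),
    s4 = c(1L, 0L, 0L), s5 = c(1L, 0L, 0L)
  )
  grp <- paste0("s", 1:5)
  expect_equal(merge_group_indirect(feats, grp, 4)$call, c(1L, 0L, 0L))
  expect_equal(merge_group_indirect(feats, grp, 1)$call, c(1L, 1L, 0L))   # OR
  expect_equal(merge_group_indirect(feats, grp, 5)$call, c(1L, 0L, 0L))   # AND
  expect_equal(merge_group_direct(feats, grp)$call,
               merge_group_indirect(feats, grp, 1)$call)
  expect_error(merge_group_indirect(feats, grp, 6), "record_threshold")
  expect_error(merge_group_indirect(feats, character(), 1), "non-empty")
})

test_that("core-set assembly is plain set algebra", {
  expect_setequal(assemble_core_set(c("a", "b"), c("b", "c")), c("a", "b", "c"))
  expect_setequal(assemble_core_set(c("a", "b"), "c", "a"), c("b", "c"))
  expect_equal(assemble_core_set(character(), character(), "x"), character())
})

test_that("a single perfect predictor separates classes completely", {
  catl <- toy_catalog(30, 50)
  feats <- generate_predictor_calls(catl, predictor_profiles("s", 1, 1), seed = 32)
  lr <- estimate_likelihood_ratios(feats, catl, alpha = 1)
  sc <- integrate_evidence(feats, lr)
  expect_equal(roc_auc(roc_curve(sc$log_lr, catl$label)), 1)
})

test_that("estimated L1 converges to the generating odds ratio", {
  cfg <- synth_config(n_pos = 1e5, n_neg = 1e5,
                      profiles = predictor_profiles("s", 0.45, 0.92), seed = 33)
  catl <- generate_gold_standard(cfg)
  feats <- generate_predictor_calls(catl, cfg$profiles, seed = 33)
  lr <- estimate_likelihood_ratios(feats, catl, alpha = 1)
  expect_lt(abs(lr$L1 - 0.45 / 0.08) / (0.45 / 0.08), 0.05)
})
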