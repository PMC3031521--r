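test_that("neighbourhood levels follow the shortest-path definitions", {
  net <- suppressMessages(pin_network(
    data.frame(from = c("a", "b", "x"), to = c("b", "c", "x2"))))
  expect_equal(neighborhood(net, "a", "N_incl"), c("a", "b"))
  expect_equal(neighborhood(net, "a", "L1"), "b")
  expect_equal(neighborhood(net, "a", "L2"), "c")
  # triangle: everything at distance 1, L2 empty
  tri <- pin_network(data.frame(from = c("a", "a", "b"), to = c("b", "c", "c")))
  expect_equal(neighborhood(tri, "a", "L2"), character())
  # isolated node
  iso <- pin_network(data.frame(from = "a", to = "b"), nodes = c("a", "b", "z"))
  expect_equal(neighborhood(iso, "z", "N_incl"), "z")
  expect_equal(neighborhood(iso, "z", "L1"), character())
  expect_error(neighborhood(net, "nope"), "unknown")
})

test_that("CD similarity matches hand enumeration on the path graph", {
  net <- path_net()
  expect_equal(cd_similarity(net, "a", "b"), 0.8)   # 2*2/(2+3)
  expect_equal(cd_similarity(net, "a", "a"), 1)
  iso <- pin_network(data.frame(from = "x", to = "y"), nodes = c("x", "y", "u", "v"))
  expect_equal(cd_similarity(iso, "u", "v"), 0)
})

test_that("transitive similarity multiplies path similarities and caps at one", {
  net <- path_net()
  expect_equal(transitive_similarity(net, "a", "c"), 0.64)
  expect_equal(transitive_similarity(net, "a", "c"),
               transitive_similarity(net, "c", "a"))
  # no common neighbour
  expect_equal(transitive_similarity(net, "a", "b"), 0)
  # u = v with neighbours: sum of squared similarities, capped
  star <- pin_network(data.frame(from = rep("h", 4), to = paste0("s", 1:4)))
  s1s <- vapply(paste0("s", 1:4), function(v) cd_similarity(star, "h", v), numeric(1))
  expect_equal(transitive_similarity(star, "h", "h"), min(1, sum(s1s^2)))
})

test_that("similarities are symmetric and bounded on random graphs", {
  withr::local_seed(50)
  for (trial in 1:5) {
    n <- 15
    ids <- sprintf("n%02d", 1:n)
    m <- matrix(runif(n * n) < 0.2, n, n)
    edges <- which(m & upper.tri(m), arr.ind = TRUE)
    net <- suppressMessages(pin_network(
      data.frame(from = ids[edges[, 1]], to = ids[edges[, 2]]), nodes = ids))
    for (pair in 1:10) {
      uv <- sample(ids, 2)
      s1 <- cd_similarity(net, uv[1], uv[2])
      s2 <- transitive_similarity(net, uv[1], uv[2])
      expect_equal(s1, cd_similarity(net, uv[2], uv[1]))
      expect_equal(s2, transitive_similarity(net, uv[2], uv[1]))
      expect_true(s1 >= 0 && s1 <= 1 && s2 >= 0 && s2 <= 1)
    }
  }
})

test_that("FunScore reproduces the hand-computed path example and its limits", {
  net <- path_net()
  ann <- tibble::tibble(protein_id = "b", term_id = "x", level = 4L)
  bg <- list(r_int = 1, pi = c(x = 0.5))
  got <- fun_score(net, ann, "a", "x", funscore_params(), background = bg)
  expect_equal(got, (1 * 1 * 0.5 + 0.8 * 1 + 0.64 * 0) / (1 + 0.8 + 0.64))

  # isolated protein with r_int > 0 falls back to the background frequency
  iso <- pin_network(data.frame(from = "m", to = "n"), nodes = c("m", "n", "z"))
  expect_equal(fun_score(iso, ann, "z", "x", background = bg), 0.5)
  # no annotated neighbour and zero background frequency -> 0
  expect_equal(fun_score(net, ann, "a", "x",
                         background = list(r_int = 1, pi = c(x = 0))), 0.8 / 2.44)
  # term carried by no neighbour of a, with zero background frequency -> 0
  got0 <- fun_score(net, tibble::tibble(protein_id = "c", term_id = "y", level = 4L),
                    "a", "x", background = list(r_int = 1, pi = c(x = 0)))
  expect_equal(got0, 0)
  # isolated protein with r_int = 0: undefined marker
  expect_true(is.na(fun_score(iso, ann, "z", "x",
                              background = list(r_int = 0, pi = c(x = 0.5)))))
})

test_that("candidate flags apply the score cutoff and empty targets return empty", {
  net <- path_net()
  ann <- tibble::tibble(protein_id = "b", term_id = "x", level = 4L)
  res <- predict_functions(net, ann, c("a", "c"))
  expect_true(all(res$candidate == (res$score >= 0.03)))
  expect_equal(nrow(predict_functions(net, ann, character())), 0)
})

test_that("scores for different terms of one protein share the same normaliser", {
  cfg <- synth_config(n_pos = 40, n_neg = 60, seed = 51, n_modules = 4,
                      module_size = 10, p_within = 0.7, p_between = 0.02,
                      coherence = 0.8, unannotated_frac = 0.1, n_terms = 6)
  catl <- generate_gold_standard(cfg)
  pin <- generate_pin(catl, cfg)
  bg <- annotation_background(pin$network, pin$annotations)
  targets <- pin$modules$protein_id[1:5]
  res <- predict_functions(pin$network, pin$annotations, targets)
  expect_true(all(res$score >= 0 & res$score <= 1, na.rm = TRUE))
  # Z cancels: sum over terms of (score - bg_term/Z) proportionality check via
  # reconstruction per protein: all scores of one protein recomputed with a
  # common Z must reproduce predict_functions exactly
  p <- targets[1]
  per_term <- vapply(names(bg$pi), function(x)
    fun_score(pin$network, pin$annotations, p, x), numeric(1))
  got <- res$score[res$protein_id == p][match(names(bg$pi),
                                              res$term_id[res$protein_id == p])]
  expect_equal(unname(per_term), got)
})

test_that("hidden planted-module annotations are recovered as the top term", {
  cfg <- synth_config(n_pos = 100, n_neg = 200, seed = 52, n_modules = 8,
                      module_size = 12, p_within = 0.8, p_between = 0.005,
                      coherence = 0.9, unannotated_frac = 0.1)
  catl <- generate_gold_standard(cfg)
  pin <- generate_pin(catl, cfg)
  mem <- pin$modules
  hidden <- mem$protein_id[seq(1, nrow(mem), by = 4)]
  ann <- pin$annotations[!pin$annotations$protein_id %in% hidden, ]
  res <- predict_functions(pin$network, ann, hidden)
  top1 <- dplyr::slice_max(dplyr::group_by(res, protein_id), score,
                           n = 1, with_ties = FALSE)
  truth <- mem$module_term[match(top1$protein_id, mem$protein_id)]
  expect_gte(mean(top1$term_id == truth), 0.9)
})

test_that("permutation p-values hit the exact extremes and are reproducible", {
  net <- path_net()
  ann <- tibble::tibble(protein_id = c("b", "c"), term_id = c("x", "x"), level = 4L)
  res <- predict_functions(net, ann, "a")
  p <- funscore_params(n_perm = 200, seed = 7)
  pv <- permutation_pvalues(net, ann, res, p)
  # both annotated proteins carry x, so every permutation reproduces the
  # observed score: p = 1
  expect_equal(pv$p_value[pv$term_id == "x"], 1)
  pv2 <- permutation_pvalues(net, ann, res, p)
  expect_equal(pv, pv2)
})

test_that("an observed score beating every permutation gets the minimal p-value", {
  # b annotated x, c annotated y: permutations swap them half the time
  net <- path_net()
  ann <- tibble::tibble(protein_id = c("b", "c"), term_id = c("x", "y"), level = 4L)
  res <- predict_functions(net, ann, "a")
  pv <- permutation_pvalues(net, ann, res, funscore_params(n_perm = 1000, seed = 8))
  # L1 neighbour b carries x with weight 0.8 > L2 weight 0.64; identity
  # permutations keep score, swaps lower it, so p ~ fraction of identity + 1
  px <- pv$p_value[pv$term_id == "x"]
  expect_true(px > 0.4 && px < 0.6)
  expect_true(all(pv$p_value > 0 & pv$p_value <= 1))
})
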