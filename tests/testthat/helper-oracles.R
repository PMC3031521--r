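# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths: plain loops and closed-form arithmetic.

# all-pairs Euclidean N50 oracle: explicit per-gene distance computation,
# ties broken by ascending gene id
oracle_n50 <- function(expr_tbl, gsp_ids, k) {
  genes <- expr_tbl$gene_id
  x <- as.matrix(expr_tbl[setdiff(names(expr_tbl), "gene_id")])
  n <- length(genes)
  counts <- integer(n)
  for (i in seq_len(n)) {
    d <- numeric(n)
    for (j in seq_len(n)) d[j] <- sqrt(sum((x[i, ] - x[j, ])^2))
    cand <- setdiff(seq_len(n), i)
    cand <- cand[order(d[cand], genes[cand])]
    counts[i] <- sum(genes[cand[seq_len(k)]] %in% gsp_ids)
  }
  counts
}

# Mann-Whitney AUC oracle: enumerate positive-negative pairs, ties count 1/2
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# hypergeometric upper tail by direct combinatorial summation
oracle_hyper <- function(k, K, N, n) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# tiny labelled catalog + perfectly separable features
toy_catalog <- function(n_pos = 5, n_neg = 5) {
  protein_catalog(
    sprintf("p%02d", seq_len(n_pos + n_neg)),
    rep(c("positive", "negative"), c(n_pos, n_neg))
  )
}

# path graph a-b-c used by the hand-derived similarity examples
path_net <- function() {
  suppressMessages(pin_network(data.frame(from = c("a", "b"), to = c("b", "c"))))
}
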