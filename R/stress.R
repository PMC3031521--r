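#' Induce a stress protein interaction subnetwork (SPIN)
#'
#' Keeps every edge with at least one endpoint in the seed set, together
#' with all incident nodes. Because interactors of seed genes are
#' retained, the subnetwork typically contains more proteins than there
#' are seeds.
#'
#' @param net A [pin_network()].
#' @param seeds Character vector of seed gene ids, or a tibble with a
#'   `gene_id` column (e.g. from [generate_stress_genes()]).
#' @return A [pin_network()] restricted to the retained edges; every edge
#'   is present in the input network.
#' @examples
#' net <- pin_network(data.frame(from = c("a", "b"), to = c("b", "c")))
#' induce_spin(net, "b")
#' @export
induce_spin <- function(net, seeds) {
  if (is.data.frame(seeds)) seeds <- seeds$gene_id
  seeds <- unique(as.character(seeds))
  keep <- net$from %in% seeds | net$to %in% seeds
  kept <- as_tibble(net)[keep, c("from", "to")]
  suppressMessages(pin_network(kept))
}

#' Hypergeometric term enrichment with Benjamini-Hochberg correction
#'
#' For every term annotated to at least one query protein, tests
#' overrepresentation of the term in the query set against the universe
#' with the hypergeometric upper tail
#' `p = sum_{i >= k} C(K,i) C(N-K, n-i) / C(N,n)` (`k` overlap, `n` query
#' size, `K` term size in the universe, `N` universe size), then adjusts
#' over all tested terms with the Benjamini-Hochberg step-up procedure.
#' Terms with zero overlap are not tested.
#'
#' @param query Character vector of query protein ids (must be a subset of
#'   the universe).
#' @param annotations Annotation tibble.
#' @param universe Character vector of universe protein ids; defaults to
#'   all annotated proteins.
#' @return A tibble with columns `term_id`, `k`, `n`, `K`, `N`, `p`, `q`,
#'   sorted by `q` then `p`.
#' @export
hypergeom_enrichment <- function(query, annotations, universe = NULL) {
  ann <- distinct(annotations[, c("protein_id", "term_id")])
  if (is.null(universe)) universe <- unique(ann$protein_id)
  universe <- unique(as.character(universe))
  if (length(universe) == 0) abort("empty universe")
  query <- unique(as.character(query))
  if (!all(query %in% universe)) abort("query must be a subset of the universe")
  ann <- ann[ann$protein_id %in% universe, ]
  if (nrow(ann) == 0) abort("no annotated proteins in the universe")
  n <- length(query)
  N <- length(universe)
  in_query <- ann$protein_id %in% query
  k_tab <- table(ann$term_id[in_query])
  if (length(k_tab) == 0) {
    return(tibble(term_id = character(), k = integer(), n = integer(),
                  K = integer(), N = integer(), p = numeric(), q = numeric()))
  }
  K_tab <- table(ann$term_id)
  terms <- names(k_tab)
  k <- as.integer(k_tab)
  K <- as.integer(K_tab[terms])
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- tibble(
    term_id = terms, k = k, n = n, K = K, N = N,
    p = p, q = p.adjust(p, method = "BH")
  )
  arrange(out, .data$q, .data$p, .data$term_id)
}
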