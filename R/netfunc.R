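#' FunScore parameters
#'
#' Tunables of the network-based function-inference score. `lambda`
#' weights the background-frequency term (1 in the published setting);
#' `cutoff` is the preliminary filtration threshold on the score (0.03);
#' `n_perm` the number of annotation permutations used for empirical
#' p-values (10,000 in the published setting). `s2_mode` chooses how
#' transitive (level-2) similarity aggregates over shared intermediate
#' neighbours: the default `"sum"` adds the per-path products and caps at
#' 1; `"max"` takes the best single path.
#'
#' @param lambda Background weight, `>= 0`. Default 1.
#' @param cutoff Score filtration threshold. Default 0.03.
#' @param n_perm Number of permutations, `>= 1`. Default 10000.
#' @param seed Integer seed for the permutations.
#' @param s2_mode `"sum"` or `"max"`.
#' @return A list of class `funscore_params`.
#' @export
funscore_params <- function(lambda = 1, cutoff = 0.03, n_perm = 10000L,
                            seed = 1L, s2_mode = c("sum", "max")) {
  if (lambda < 0) abort("lambda must be >= 0")
  if (n_perm < 1) abort("n_perm must be >= 1")
  structure(
    list(lambda = lambda, cutoff = cutoff, n_perm = as.integer(n_perm),
         seed = as.integer(seed), s2_mode = match.arg(s2_mode)),
    class = "funscore_params"
  )
}

# adjacency list: named list, node -> character vector of neighbours
adjacency_list <- function(net) {
  nodes <- pin_nodes(net)
  adj <- split(c(net$to, net$from), c(net$from, net$to))
  out <- setNames(vector("list", length(nodes)), nodes)
  out[names(adj)] <- lapply(adj, unique)
  out[vapply(out, is.null, logical(1))] <- list(character())
  out
}

#' Interaction neighbourhoods of a protein
#'
#' `"N_incl"` is the inclusive neighbourhood (the protein plus its direct
#' interactors) used inside the Czekanowski-Dice similarity; `"L1"` the
#' direct interactors; `"L2"` the proteins at shortest-path distance
#' exactly 2.
#'
#' @param net A [pin_network()].
#' @param p Protein id, must be a network node.
#' @param level One of `"N_incl"`, `"L1"`, `"L2"`.
#' @return Character vector of protein ids.
#' @examples
#' net <- pin_network(data.frame(from = c("a", "b"), to = c("b", "c")))
#' neighborhood(net, "a", "L2")
#' @export
neighborhood <- function(net, p, level = c("N_incl", "L1", "L2")) {
  level <- match.arg(level)
  nodes <- pin_nodes(net)
  if (!p %in% nodes) abort(paste0("unknown protein: ", p))
  adj <- adjacency_list(net)
  l1 <- adj[[p]]
  switch(level,
    N_incl = sort(union(p, l1)),
    L1 = sort(l1),
    L2 = sort(setdiff(unique(unlist(adj[l1], use.names = FALSE)), c(p, l1)))
  )
}

cd_sim_sets <- function(nu, nv) {
  2 * length(intersect(nu, nv)) / (length(nu) + length(nv))
}

#' Czekanowski-Dice functional similarity
#'
#' With `Nu`, `Nv` the inclusive neighbourhoods of `u` and `v`, the
#' Czekanowski-Dice distance is `|Nu delta Nv| / (|Nu| + |Nv|)` and the
#' similarity reported here is its complement
#' `S1 = 2 |Nu intersect Nv| / (|Nu| + |Nv|)`, in \[0, 1\].
#'
#' @param net A [pin_network()].
#' @param u,v Protein ids (network nodes).
#' @return Similarity in \[0, 1\].
#' @examples
#' net <- pin_network(data.frame(from = c("a", "b"), to = c("b", "c")))
#' cd_similarity(net, "a", "b")  # 0.8
#' @export
cd_similarity <- function(net, u, v) {
  adj <- adjacency_list(net)
  nodes <- pin_nodes(net)
  if (!u %in% nodes || !v %in% nodes) abort("u and v must be network nodes")
  cd_sim_sets(union(u, adj[[u]]), union(v, adj[[v]]))
}

#' Transitive (level-2) functional similarity
#'
#' Association carried through shared intermediate neighbours: for every
#' `w` adjacent to both `u` and `v` (excluding `u`, `v` themselves) the
#' path contributes the product `S1(u,w) * S1(w,v)`; contributions are
#' summed and capped at 1 (or maximised, see [funscore_params()]'s
#' `s2_mode`). Symmetric in `u`, `v`.
#'
#' @inheritParams cd_similarity
#' @param s2_mode `"sum"` (default) or `"max"`.
#' @return Similarity in \[0, 1\].
#' @export
transitive_similarity <- function(net, u, v, s2_mode = c("sum", "max")) {
  s2_mode <- match.arg(s2_mode)
  adj <- adjacency_list(net)
  nodes <- pin_nodes(net)
  if (!u %in% nodes || !v %in% nodes) abort("u and v must be network nodes")
  common <- setdiff(intersect(adj[[u]], adj[[v]]), c(u, v))
  if (length(common) == 0) return(0)
  nu <- union(u, adj[[u]]); nv <- union(v, adj[[v]])
  paths <- vapply(common, function(w) {
    nw <- union(w, adj[[w]])
    cd_sim_sets(nu, nw) * cd_sim_sets(nw, nv)
  }, numeric(1))
  if (s2_mode == "sum") min(1, sum(paths)) else max(paths)
}

#' Background annotation statistics of a network
#'
#' `r_int` is the fraction of edges whose two endpoints are both annotated
#' and share at least one function term, computed over both-annotated
#' edges only; `pi` maps each term to its frequency among annotated
#' proteins.
#'
#' @param net A [pin_network()].
#' @param annotations Annotation tibble.
#' @return A list with `r_int` (scalar) and `pi` (named numeric vector).
#' @export
annotation_background <- function(net, annotations) {
  ann_sets <- split(annotations$term_id, annotations$protein_id)
  annotated <- names(ann_sets)
  both <- net$from %in% annotated & net$to %in% annotated
  if (sum(both) == 0) {
    r_int <- 0
  } else {
    share <- mapply(function(a, b) length(intersect(ann_sets[[a]], ann_sets[[b]])) > 0,
                    net$from[both], net$to[both])
    r_int <- mean(share)
  }
  n_ann <- length(annotated)
  pi <- table(unique(annotations[, c("protein_id", "term_id")])$term_id) / n_ann
  list(r_int = r_int, pi = setNames(as.numeric(pi), names(pi)))
}

# Precomputed scoring machinery shared by fun_score / predict_functions /
# permutation_pvalues: per-target neighbour weights (S1 on L1, S2 on L2)
# assembled into a dense weight matrix, the normaliser Z, and the
# background statistics. Only the annotation assignment varies afterwards,
# so permutation scoring reduces to one matrix product per permutation.
funscore_machine <- function(net, annotations, targets, params,
                             background = NULL) {
  adj <- adjacency_list(net)
  nodes <- names(adj)
  bad <- setdiff(targets, nodes)
  if (length(bad) > 0) abort(paste0("targets not in network: ", paste(head(bad, 5), collapse = ", ")))
  if (is.null(background)) background <- annotation_background(net, annotations)
  incl <- lapply(nodes, function(p) union(p, adj[[p]]))
  names(incl) <- nodes
  weights <- lapply(targets, function(p) {
    l1 <- adj[[p]]
    l2 <- setdiff(unique(unlist(adj[l1], use.names = FALSE)), c(p, l1))
    w1 <- vapply(l1, function(v) cd_sim_sets(incl[[p]], incl[[v]]), numeric(1))
    w2 <- vapply(l2, function(w) {
      common <- setdiff(intersect(adj[[p]], adj[[w]]), c(p, w))
      paths <- vapply(common, function(m) {
        cd_sim_sets(incl[[p]], incl[[m]]) * cd_sim_sets(incl[[m]], incl[[w]])
      }, numeric(1))
      if (params$s2_mode == "sum") min(1, sum(paths)) else
        if (length(paths)) max(paths) else 0
    }, numeric(1))
    c(setNames(w1, l1), setNames(w2, l2))
  })
  names(weights) <- targets
  nb_proteins <- sort(unique(unlist(lapply(weights, names), use.names = FALSE)))
  W <- matrix(0, length(targets), length(nb_proteins),
              dimnames = list(targets, nb_proteins))
  for (i in seq_along(targets)) {
    w <- weights[[i]]
    W[i, names(w)] <- w
  }
  z <- vapply(weights, sum, numeric(1)) + params$lambda * background$r_int
  list(W = W, z = z, background = background, targets = targets)
}

# indicator matrix (neighbour proteins x terms) for an annotation-set
# assignment given as a named list protein -> term vector
ann_indicator <- function(ann_sets, proteins, terms) {
  A <- matrix(0, length(proteins), length(terms),
              dimnames = list(proteins, terms))
  prot <- rep(names(ann_sets), lengths(ann_sets))
  term <- unlist(ann_sets, use.names = FALSE)
  i <- match(prot, proteins)
  j <- match(term, terms)
  keep <- !is.na(i) & !is.na(j)
  A[cbind(i[keep], j[keep])] <- 1
  A
}

# score matrix (targets x terms) given a protein -> term-set assignment
machine_scores <- function(machine, ann_sets, params) {
  terms <- names(machine$background$pi)
  bg <- params$lambda * machine$background$r_int * machine$background$pi[terms]
  A <- ann_indicator(ann_sets, colnames(machine$W), terms)
  S <- machine$W %*% A
  out <- sweep(S, 2, bg, "+") / machine$z
  out[machine$z == 0, ] <- NA_real_  # undefined-score marker
  out
}

#' FunScore of a single protein-function pair
#'
#' The normalised weighted vote that protein `p` carries function `x`:
#' `(lambda * r_int * pi_x + sum over level-1 neighbours v of
#' S1(p,v) * delta(v,x) + sum over level-2 neighbours w of
#' S2(p,w) * delta(w,x)) / Z` with
#' `Z = lambda * r_int + sum S1 + sum S2`. The result lies in \[0, 1\];
#' it is `NA` (undefined) for an isolated protein when `r_int = 0`.
#'
#' @param net A [pin_network()].
#' @param annotations Annotation tibble.
#' @param p Protein id (network node).
#' @param x Term id present in the annotation table.
#' @param params A [funscore_params()].
#' @param background Optional list with `r_int` and `pi` overriding
#'   [annotation_background()] (useful for sensitivity analysis).
#' @return The score, a number in \[0, 1\] or `NA`.
#' @export
fun_score <- function(net, annotations, p, x, params = funscore_params(),
                      background = NULL) {
  machine <- funscore_machine(net, annotations, p, params, background = background)
  if (!x %in% names(machine$background$pi)) {
    abort(paste0("term ", x, " absent from the annotation background"))
  }
  ann_sets <- split(annotations$term_id, annotations$protein_id)
  machine_scores(machine, ann_sets, params)[p, x]
}

#' Score candidate functions for target proteins
#'
#' Computes the FunScore of every (target, term) pair over all terms with
#' non-zero background frequency and flags pairs at or above the
#' filtration cutoff as candidates.
#'
#' @param net A [pin_network()].
#' @param annotations Annotation tibble.
#' @param targets Character vector of proteins to score (network nodes);
#'   typically the unannotated members of the core mitochondrial set.
#' @param params A [funscore_params()].
#' @param background Optional list with `r_int` and `pi` overriding
#'   [annotation_background()].
#' @return A tibble of class `funscore_result` with columns `protein_id`,
#'   `term_id`, `score`, `candidate`.
#' @export
predict_functions <- function(net, annotations, targets, params = funscore_params(),
                              background = NULL) {
  if (length(targets) == 0) {
    out <- tibble(protein_id = character(), term_id = character(),
                  score = numeric(), candidate = logical())
    return(structure(out, params = params, class = c("funscore_result", class(out))))
  }
  machine <- funscore_machine(net, annotations, targets, params,
                              background = background)
  ann_sets <- split(annotations$term_id, annotations$protein_id)
  sc <- machine_scores(machine, ann_sets, params)
  out <- tibble(
    protein_id = rep(rownames(sc), times = ncol(sc)),
    term_id = rep(colnames(sc), each = nrow(sc)),
    score = as.vector(sc)
  )
  out <- arrange(out, .data$protein_id, dplyr::desc(.data$score))
  out$candidate <- !is.na(out$score) & out$score >= params$cutoff
  structure(out, params = params, class = c("funscore_result", class(out)))
}

#' Permutation p-values for scored protein-function pairs
#'
#' Builds the null distribution of each pair's FunScore by repeatedly
#' shuffling the protein-to-annotation-set assignment among annotated
#' proteins (the network and each protein's annotation count are
#' preserved, as are the term background frequencies; the network-derived
#' weights stay fixed). The empirical p-value is
#' `(1 + #permuted >= observed) / (n_perm + 1)`; a pair is significant
#' when `p < 0.05` and its observed score passed the cutoff.
#'
#' @param net A [pin_network()].
#' @param annotations Annotation tibble (the observed assignment).
#' @param result A [predict_functions()] result.
#' @param params A [funscore_params()]; `n_perm` and `seed` control the
#'   permutations.
#' @param background Optional list with `r_int` and `pi` overriding
#'   [annotation_background()]; must match what produced `result`.
#' @return `result` with `p_value` and `significant` columns added.
#' @export
permutation_pvalues <- function(net, annotations, result,
                                params = funscore_params(),
                                background = NULL) {
  if (nrow(result) == 0) {
    result$p_value <- numeric(0)
    result$significant <- logical(0)
    return(result)
  }
  targets <- unique(result$protein_id)
  machine <- funscore_machine(net, annotations, targets, params,
                              background = background)
  ann_sets <- split(annotations$term_id, annotations$protein_id)
  annotated <- names(ann_sets)
  obs <- machine_scores(machine, ann_sets, params)
  idx <- cbind(match(result$protein_id, rownames(obs)),
               match(result$term_id, colnames(obs)))
  observed <- obs[idx]
  exceed <- integer(nrow(result))
  with_seed(derive_seed(params$seed, "funscore_perm"), {
    for (b in seq_len(params$n_perm)) {
      perm <- sample(annotated)
      perm_sets <- setNames(ann_sets, perm)
      sc <- machine_scores(machine, perm_sets, params)
      exceed <- exceed + (!is.na(observed) & sc[idx] >= observed)
    }
  })
  result$p_value <- ifelse(is.na(observed), NA_real_,
                           (1 + exceed) / (params$n_perm + 1))
  result$significant <- !is.na(result$p_value) &
    result$p_value < 0.05 & result$candidate
  result
}
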