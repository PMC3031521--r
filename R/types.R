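#' Construct a gold-standard protein catalog
#'
#' A protein catalog records, for each protein, whether it belongs to the
#' gold-standard positive set (experimentally verified mitochondrial
#' proteins), the gold-standard negative set (verified non-mitochondrial
#' proteins), or is unlabelled. The positive and negative sets must be
#' disjoint, mirroring how the training sets are curated.
#'
#' @param protein_id Character vector of unique protein identifiers
#'   (opaque, case-sensitive tokens such as AGI locus symbols).
#' @param label Character vector, one of `"positive"`, `"negative"`,
#'   `"unknown"`, recycled if length 1.
#' @param source Optional free-text provenance tag per protein.
#'
#' @return A tibble with columns `protein_id`, `label`, `source`.
#' @examples
#' protein_catalog(c("AT1G01010", "AT1G01020"), c("positive", "negative"))
#' @export
protein_catalog <- function(protein_id, label = "unknown", source = NA_character_) {
  cat <- tibble(
    protein_id = as.character(protein_id),
    label = as.character(label),
    source = as.character(source)
  )
  validate_catalog(cat)
}

catalog_labels <- c("positive", "negative", "unknown")

#' Validate a protein catalog
#'
#' Checks identifier uniqueness and that labels come from the allowed set.
#' All functions taking a `catalog` argument accept any data frame with
#' `protein_id` and `label` columns that passes this check.
#'
#' @param catalog A data frame with columns `protein_id` and `label`.
#' @return The catalog as a tibble, invisibly validated.
#' @export
validate_catalog <- function(catalog) {
  catalog <- as_tibble(catalog)
  req <- c("protein_id", "label")
  if (!all(req %in% names(catalog))) {
    abort(paste0("catalog must have columns: ", paste(req, collapse = ", ")))
  }
  if (anyDuplicated(catalog$protein_id)) {
    dup <- unique(catalog$protein_id[duplicated(catalog$protein_id)])
    abort(paste0("duplicate protein ids in catalog: ", paste(head(dup, 5), collapse = ", ")))
  }
  bad <- setdiff(unique(catalog$label), catalog_labels)
  if (length(bad) > 0) {
    abort(paste0("invalid labels: ", paste(bad, collapse = ", "),
                 " (allowed: ", paste(catalog_labels, collapse = ", "), ")"))
  }
  if (!"source" %in% names(catalog)) catalog$source <- NA_character_
  catalog
}

positives <- function(catalog) catalog$protein_id[catalog$label == "positive"]
negatives <- function(catalog) catalog$protein_id[catalog$label == "negative"]

#' Validate a binary feature matrix
#'
#' A feature matrix is a wide tibble: a `protein_id` column followed by one
#' column per predictor, with calls coded 1 (predicted mitochondrial),
#' 0 (predicted non-mitochondrial) or `NA` (the predictor did not score the
#' protein).
#'
#' @param features Data frame with `protein_id` plus predictor columns.
#' @return The features as a tibble.
#' @export
validate_features <- function(features) {
  features <- as_tibble(features)
  if (!"protein_id" %in% names(features)) {
    abort("feature matrix must have a protein_id column")
  }
  if (ncol(features) < 2) abort("feature matrix has no predictor columns")
  if (anyDuplicated(features$protein_id)) {
    abort("duplicate protein ids in feature matrix")
  }
  vals <- unlist(features[setdiff(names(features), "protein_id")], use.names = FALSE)
  ok <- is.na(vals) | vals %in% c(0, 1)
  if (!all(ok)) abort("feature calls must be 0, 1 or missing (NA)")
  features
}

predictor_ids <- function(features) setdiff(names(features), "protein_id")

#' Construct a protein interaction network
#'
#' Networks are undirected and unweighted: an edge tibble with columns
#' `from` and `to`, canonicalised so that `from < to`, with self-loops and
#' duplicate (including reciprocal) edges removed. Isolated nodes are kept
#' in the `nodes` attribute so that neighbourhood queries work for proteins
#' without interactions.
#'
#' @param edges Data frame with character columns `from`, `to`.
#' @param nodes Optional character vector of node ids; defaults to the
#'   endpoints present in `edges`. Endpoints not listed are added.
#'
#' @return A tibble of canonical edges with class `mito_pin` and a `nodes`
#'   attribute.
#' @examples
#' pin_network(data.frame(from = c("a", "b"), to = c("b", "a")))
#' @export
pin_network <- function(edges, nodes = NULL) {
  edges <- as_tibble(edges)
  if (nrow(edges) > 0 && !all(c("from", "to") %in% names(edges))) {
    abort("edges must have columns from, to")
  }
  if (nrow(edges) == 0) {
    edges <- tibble(from = character(), to = character())
  }
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  loops <- edges$from == edges$to
  n_loops <- sum(loops)
  if (n_loops > 0) {
    inform(paste0("dropped ", n_loops, " self-loop(s)"))
    edges <- edges[!loops, , drop = FALSE]
  }
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  canon <- tibble(from = a, to = b)
  n_before <- nrow(canon)
  canon <- distinct(canon)
  if (nrow(canon) < n_before) {
    inform(paste0("collapsed ", n_before - nrow(canon), " duplicate/reciprocal edge(s)"))
  }
  canon <- arrange(canon, .data$from, .data$to)
  all_nodes <- sort(unique(c(nodes, canon$from, canon$to)))
  structure(canon, nodes = all_nodes, class = c("mito_pin", class(canon)))
}

#' @export
print.mito_pin <- function(x, ...) {
  cat("<protein interaction network> ", length(attr(x, "nodes")), " nodes, ",
      nrow(x), " edges\n", sep = "")
  NextMethod()
}

pin_nodes <- function(net) attr(net, "nodes") %||% sort(unique(c(net$from, net$to)))

# igraph view of a mito_pin, keeping isolated nodes
pin_igraph <- function(net) {
  igraph::graph_from_data_frame(
    as.data.frame(net[, c("from", "to")]),
    directed = FALSE,
    vertices = data.frame(name = pin_nodes(net))
  )
}

#' Validate a protein-to-function annotation table
#'
#' Annotation records are (protein, term, level) triples; levels tag the
#' depth of the term in the function hierarchy (the analysis restricts
#' itself to mid-depth levels, 4 and 5 by default, so that term background
#' frequencies are neither ubiquitous nor vanishing).
#'
#' @param annotations Data frame with columns `protein_id`, `term_id`,
#'   `level` (integer).
#' @param allowed_levels Integer vector of admissible levels.
#' @return De-duplicated annotation tibble restricted to `allowed_levels`.
#' @export
validate_annotations <- function(annotations, allowed_levels = c(4L, 5L)) {
  annotations <- as_tibble(annotations)
  req <- c("protein_id", "term_id", "level")
  if (!all(req %in% names(annotations))) {
    abort(paste0("annotations must have columns: ", paste(req, collapse = ", ")))
  }
  if (!is.numeric(annotations$level) || any(annotations$level %% 1 != 0, na.rm = TRUE)) {
    abort("annotation levels must be integers")
  }
  keep <- annotations$level %in% allowed_levels
  if (any(!keep)) {
    inform(paste0("dropped ", sum(!keep), " record(s) outside levels {",
                  paste(allowed_levels, collapse = ","), "}"))
  }
  distinct(annotations[keep, req])
}
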