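#' Read a protein-by-predictor call table
#'
#' Expects a header-bearing TSV whose first column holds protein ids and
#' whose remaining columns hold one binary call per predictor. Cells equal
#' to `missing_token` become `NA` (the predictor did not score the protein);
#' all other cells must be 0 or 1.
#'
#' @param path Path to a tab-separated file.
#' @param missing_token String encoding a missing call. Default `"NA"`.
#' @return A validated feature tibble (see [validate_features()]).
#' @export
read_feature_table <- function(path, missing_token = "NA") {
  lines <- readr::read_lines(path)
  if (length(lines) < 1) abort("empty feature table")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  width <- length(fields[[1]])
  widths <- lengths(fields)
  if (any(widths != width)) {
    bad <- which(widths != width)[1]
    abort(paste0("malformed row at line ", bad, ": expected ", width,
                 " fields, found ", widths[bad]))
  }
  header <- fields[[1]]
  body <- fields[-1]
  ids <- vapply(body, `[[`, character(1), 1)
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate protein id: ", ids[duplicated(ids)][1]))
  }
  parse_call <- function(x) {
    out <- rep(NA_integer_, length(x))
    out[x == "1"] <- 1L
    out[x == "0"] <- 0L
    bad <- !(x %in% c("0", "1", missing_token))
    if (any(bad)) abort(paste0("unparseable call value: ", x[bad][1]))
    out
  }
  calls <- lapply(seq_len(width - 1) + 1, function(j) {
    parse_call(vapply(body, `[[`, character(1), j))
  })
  out <- tibble(protein_id = ids)
  for (j in seq_along(calls)) out[[header[j + 1]]] <- calls[[j]]
  validate_features(out)
}

#' Write a feature table as TSV
#'
#' Inverse of [read_feature_table()]; `NA` calls are written as
#' `missing_token`.
#'
#' @inheritParams read_feature_table
#' @param features Feature tibble.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path, missing_token = "NA") {
  features <- validate_features(features)
  readr::write_tsv(features, path, na = missing_token)
  invisible(path)
}

#' Read an undirected protein interaction edge list
#'
#' Two tab-separated id columns per line. Reciprocal and duplicate lines
#' collapse to one undirected edge; self-loops are dropped (a count is
#' reported via a message).
#'
#' @param path Path to a TSV edge list.
#' @param header Whether the first line is a header. Default `TRUE`.
#' @return A [pin_network()] object.
#' @export
read_edge_list <- function(path, header = TRUE) {
  df <- readr::read_tsv(
    path,
    col_names = if (header) TRUE else c("from", "to"),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (nrow(df) == 0) abort("empty edge list")
  if (ncol(df) < 2) abort("edge list needs two columns")
  names(df)[1:2] <- c("from", "to")
  pin_network(df[, c("from", "to")])
}

#' Write a network edge list as TSV
#'
#' @param net A [pin_network()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  readr::write_tsv(as_tibble(net)[, c("from", "to")], path)
  invisible(path)
}

#' Read a protein-function annotation table
#'
#' Three tab-separated columns: `protein_id`, `term_id`, `level`. Records
#' at levels outside `allowed_levels` are dropped with a message; exact
#' duplicates collapse to one record.
#'
#' @param path Path to a TSV annotation table (with header).
#' @param allowed_levels Integer levels to keep; default `c(4, 5)`.
#' @return A validated annotation tibble.
#' @export
read_annotations <- function(path, allowed_levels = c(4L, 5L)) {
  df <- readr::read_tsv(
    path,
    col_types = readr::cols(
      protein_id = readr::col_character(),
      term_id = readr::col_character(),
      level = readr::col_character()
    ),
    progress = FALSE
  )
  lev <- suppressWarnings(as.numeric(df$level))
  if (any(is.na(lev) | lev %% 1 != 0)) {
    abort(paste0("non-integer level: ", df$level[is.na(lev) | lev %% 1 != 0][1]))
  }
  df$level <- as.integer(lev)
  validate_annotations(df, allowed_levels = allowed_levels)
}

#' Write an annotation table as TSV
#'
#' @param annotations Annotation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  readr::write_tsv(annotations[, c("protein_id", "term_id", "level")], path)
  invisible(path)
}

#' Read a gene-by-sample expression matrix
#'
#' Header-bearing TSV: first column `gene_id`, remaining columns one per
#' sample, all values finite numbers (normalised expression, unitless).
#'
#' @param path Path to a TSV expression matrix.
#' @return A tibble with `gene_id` plus numeric sample columns.
#' @export
read_expression <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  if (!"gene_id" %in% names(df)) abort("expression matrix must have a gene_id column")
  vals <- as.matrix(df[setdiff(names(df), "gene_id")])
  if (any(!is.finite(vals))) abort("expression values must all be finite")
  if (anyDuplicated(df$gene_id)) abort("duplicate gene ids in expression matrix")
  df
}

#' Write an expression matrix as TSV
#'
#' @param expression Expression tibble (`gene_id` + sample columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expression, path) {
  readr::write_tsv(expression, path)
  invisible(path)
}

#' Read a gold-standard catalog table
#'
#' Header-bearing TSV with columns `protein_id`, `label` and optionally
#' `source`.
#'
#' @param path Path to a TSV catalog.
#' @return A validated catalog tibble.
#' @export
read_catalog <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  validate_catalog(df)
}

#' Write a catalog as TSV
#'
#' @param catalog Catalog tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  readr::write_tsv(validate_catalog(catalog), path)
  invisible(path)
}
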