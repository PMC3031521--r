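#' Predictor operating-point profiles
#'
#' A profile gives the per-class call probabilities of one binary
#' genome-scale predictor: a positive (mitochondrial) protein is called 1
#' with probability `sensitivity`, a negative or unlabelled protein with
#' probability `1 - specificity`, independently across proteins and
#' predictors (the conditional-independence structure the naive Bayes
#' integration assumes).
#'
#' @param predictor_id Character vector of predictor names.
#' @param sensitivity,specificity Probabilities in \[0, 1\], recycled.
#' @return A tibble with columns `predictor_id`, `sensitivity`, `specificity`.
#' @export
predictor_profiles <- function(predictor_id, sensitivity, specificity) {
  out <- tibble(
    predictor_id = as.character(predictor_id),
    sensitivity = as.numeric(sensitivity),
    specificity = as.numeric(specificity)
  )
  if (any(out$sensitivity < 0 | out$sensitivity > 1 |
            out$specificity < 0 | out$specificity > 1)) {
    abort("sensitivity and specificity must lie in [0, 1]")
  }
  if (anyDuplicated(out$predictor_id)) abort("duplicate predictor ids")
  out
}

#' Reference operating points for the fourteen predictors
#'
#' The published operating points (sensitivity, specificity) of the
#' fourteen genome-scale mitochondrial-localization predictors, from the
#' targeting-signal tools (s1-s9), the ancestry/ortholog mappings
#' (s10-s13) and the N50 coexpression classifier (s14). These are the
#' default profiles the synthetic generator emulates.
#'
#' @return A 14-row profile tibble (see [predictor_profiles()]).
#' @export
reference_profiles <- function() {
  predictor_profiles(
    predictor_id = paste0("s", 1:14),
    sensitivity = c(0.5087, 0.4926, 0.4194, 0.3710, 0.3201, 0.2519, 0.2754,
                    0.1886, 0.3623, 0.3040, 0.3263, 0.2940, 0.3189, 0.5409),
    specificity = c(0.8443, 0.8969, 0.9570, 0.8668, 0.9884, 0.9693, 0.9467,
                    0.9898, 0.9440, 0.8969, 0.9809, 0.9843, 0.9816, 0.9836)
  )
}

#' Synthetic-study configuration
#'
#' Bundles the parameters of every synthetic generator. Defaults mirror the
#' study conditions the methods were developed under: 806 gold-standard
#' positives, 1,464 gold-standard negatives, the fourteen predictor
#' operating points of [reference_profiles()], multi-dataset expression
#' panels in which mitochondrial genes co-express, and an interaction
#' network with planted function-coherent modules.
#'
#' @param n_pos,n_neg,n_unknown Gold-standard class sizes.
#' @param profiles Predictor profile tibble.
#' @param n_datasets Number of expression datasets.
#' @param n_samples Samples per expression dataset.
#' @param rho Within-positive expected pairwise correlation, in \[0, 1).
#' @param noise_sd Overall expression scale (unitless normalised expression).
#' @param n_modules,module_size Planted-partition layout of the network.
#' @param p_within,p_between Edge probabilities inside a module and in the
#'   background.
#' @param coherence Probability a module member is annotated with the
#'   module's dominant term rather than a random term.
#' @param unannotated_frac Fraction of proteins left without annotations.
#' @param n_terms Size of the function-term pool.
#' @param seed Integer master seed; every generator derives an independent
#'   substream from it.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_pos = 806, n_neg = 1464, n_unknown = 0,
                         profiles = reference_profiles(),
                         n_datasets = 24, n_samples = 43, rho = 0.8,
                         noise_sd = 1,
                         n_modules = 10, module_size = 12,
                         p_within = 0.8, p_between = 0.005,
                         coherence = 0.9, unannotated_frac = 0.1,
                         n_terms = 20,
                         seed = 1L) {
  stopifnot(n_pos >= 0, n_neg >= 0, n_unknown >= 0, n_pos + n_neg + n_unknown > 0)
  if (rho < 0 || rho >= 1) abort("rho must lie in [0, 1)")
  for (p in c(p_within, p_between, coherence, unannotated_frac)) {
    if (p < 0 || p > 1) abort("probabilities must lie in [0, 1]")
  }
  structure(
    list(
      n_pos = n_pos, n_neg = n_neg, n_unknown = n_unknown,
      profiles = profiles,
      n_datasets = n_datasets, n_samples = n_samples, rho = rho,
      noise_sd = noise_sd,
      n_modules = n_modules, module_size = module_size,
      p_within = p_within, p_between = p_between,
      coherence = coherence, unannotated_frac = unannotated_frac,
      n_terms = n_terms,
      seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

# independent substream seed per generator, kept below 2^31
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  (abs(as.numeric(seed)) * 7919 + h) %% 2147483647
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic gold-standard catalog
#'
#' @param config A [synth_config()].
#' @return A catalog tibble with exactly `n_pos` positives, `n_neg`
#'   negatives and `n_unknown` unlabelled proteins; deterministic given the
#'   configuration seed.
#' @examples
#' generate_gold_standard(synth_config(n_pos = 3, n_neg = 2, seed = 1))
#' @export
generate_gold_standard <- function(config) {
  n <- config$n_pos + config$n_neg + config$n_unknown
  ids <- sprintf("P%05d", seq_len(n))
  labels <- with_seed(derive_seed(config$seed, "gold_standard"), {
    sample(rep(c("positive", "negative", "unknown"),
               c(config$n_pos, config$n_neg, config$n_unknown)))
  })
  protein_catalog(ids, labels, source = "synthetic")
}

#' Generate conditionally independent predictor calls
#'
#' For each protein and predictor independently, the call is 1 with
#' probability `sensitivity` if the protein is a gold-standard positive and
#' `1 - specificity` otherwise, matching the class-conditional independence
#' the integration model assumes.
#'
#' @param catalog Catalog tibble.
#' @param profiles Profile tibble (see [predictor_profiles()]).
#' @param seed Integer seed.
#' @return A feature tibble (`protein_id` + one 0/1 column per predictor).
#' @export
generate_predictor_calls <- function(catalog, profiles, seed = 1L) {
  catalog <- validate_catalog(catalog)
  if (nrow(profiles) == 0) abort("profiles must be non-empty")
  is_pos <- catalog$label == "positive"
  n <- nrow(catalog)
  with_seed(derive_seed(seed, "predictor_calls"), {
    out <- tibble(protein_id = catalog$protein_id)
    for (i in seq_len(nrow(profiles))) {
      p1 <- ifelse(is_pos, profiles$sensitivity[i], 1 - profiles$specificity[i])
      out[[profiles$predictor_id[i]]] <- rbinom(n, 1L, p1)
    }
    validate_features(out)
  })
}

#' Generate expression datasets with co-expressed positives
#'
#' Each dataset carries one latent per-sample factor shared by all
#' gold-standard positive genes: a positive gene's expression is
#' `sqrt(rho) * factor + sqrt(1 - rho) * noise`, so the expected pairwise
#' correlation between two positives is `rho`; negatives and unlabelled
#' genes are independent noise. All values are scaled by `noise_sd`.
#'
#' @param catalog Catalog tibble (gene ids are taken from it).
#' @param config A [synth_config()].
#' @return A named list of expression tibbles, one per dataset
#'   (`D01`, `D02`, ...).
#' @export
generate_expression <- function(catalog, config) {
  catalog <- validate_catalog(catalog)
  is_pos <- catalog$label == "positive"
  n <- nrow(catalog)
  m <- config$n_samples
  rho <- config$rho
  with_seed(derive_seed(config$seed, "expression"), {
    out <- lapply(seq_len(config$n_datasets), function(d) {
      f <- rnorm(m)
      eps <- matrix(rnorm(n * m), n, m)
      x <- eps
      if (any(is_pos)) {
        x[is_pos, ] <- sqrt(rho) * matrix(f, sum(is_pos), m, byrow = TRUE) +
          sqrt(1 - rho) * eps[is_pos, , drop = FALSE]
      }
      x <- config$noise_sd * x
      df <- tibble(gene_id = catalog$protein_id)
      colnames(x) <- sprintf("S%03d", seq_len(m))
      bind_cols(df, as_tibble(x))
    })
    names(out) <- sprintf("D%02d", seq_len(config$n_datasets))
    out
  })
}

#' Generate a planted-module interaction network with annotations
#'
#' Draws a planted-partition graph: `n_modules` disjoint modules of
#' `module_size` proteins with within-module edge probability `p_within`,
#' and background edges between any other pair with probability
#' `p_between`. Each module is assigned a dominant function term; each
#' member is annotated with that term with probability `coherence` and
#' with a uniformly random term otherwise. Non-module proteins get a
#' random term. A fraction `unannotated_frac` of proteins is left without
#' any annotation.
#'
#' @param catalog Catalog tibble supplying the protein universe.
#' @param config A [synth_config()].
#' @return A list with elements `network` (a [pin_network()]),
#'   `annotations` (annotation tibble, level 4), and `modules` (tibble
#'   mapping protein to planted module and module term, for test oracles).
#' @export
generate_pin <- function(catalog, config) {
  catalog <- validate_catalog(catalog)
  ids <- catalog$protein_id
  n <- length(ids)
  k <- config$module_size
  nm <- config$n_modules
  if (nm * k > n) abort("module_size * n_modules exceeds catalog size")
  with_seed(derive_seed(config$seed, "pin"), {
    member_idx <- sample(n, nm * k)
    module_of <- rep(NA_integer_, n)
    module_of[member_idx] <- rep(seq_len(nm), each = k)
    terms <- sprintf("T%03d", seq_len(max(config$n_terms, nm)))
    module_term <- sample(terms, nm)

    # within-module edges
    edges <- list()
    for (m in seq_len(nm)) {
      mem <- ids[which(module_of == m)]
      pairs <- utils::combn(mem, 2)
      keep <- runif(ncol(pairs)) < config$p_within
      edges[[m]] <- tibble(from = pairs[1, keep], to = pairs[2, keep])
    }
    within <- bind_rows(edges)
    # background edges over all remaining pairs, sampled sparsely
    n_pairs <- n * (n - 1) / 2
    n_bg <- rbinom(1, n_pairs, config$p_between)
    bg <- NULL
    if (n_bg > 0) {
      i <- sample(n, n_bg, replace = TRUE)
      j <- sample(n, n_bg, replace = TRUE)
      ok <- i != j
      bg <- tibble(from = ids[i[ok]], to = ids[j[ok]])
      mi <- module_of[i[ok]]; mj <- module_of[j[ok]]
      same_mod <- !is.na(mi) & !is.na(mj) & mi == mj
      bg <- bg[!same_mod, , drop = FALSE]
    }
    net <- suppressMessages(pin_network(bind_rows(within, bg), nodes = ids))

    # annotations
    ann_term <- character(n)
    in_mod <- !is.na(module_of)
    use_mod_term <- runif(n) < config$coherence
    ann_term[in_mod & use_mod_term] <- module_term[module_of[in_mod & use_mod_term]]
    random_pick <- !in_mod | !use_mod_term
    ann_term[random_pick] <- sample(terms, sum(random_pick), replace = TRUE)
    annotated <- runif(n) >= config$unannotated_frac
    annotations <- tibble(
      protein_id = ids[annotated],
      term_id = ann_term[annotated],
      level = 4L
    )
    list(
      network = net,
      annotations = validate_annotations(annotations),
      modules = tibble(
        protein_id = ids[in_mod],
        module = module_of[in_mod],
        module_term = module_term[module_of[in_mod]]
      )
    )
  })
}

#' Generate a stress-responsive seed gene list
#'
#' Samples a set of "differentially expressed" proteins to act as seeds for
#' stress-subnetwork induction, preferentially from planted-module members
#' so that the induced subnetwork is function-coherent.
#'
#' @param catalog Catalog tibble.
#' @param n_seeds Number of seed genes.
#' @param modules Optional module membership tibble from [generate_pin()];
#'   when given, seeds are drawn from module members first.
#' @param seed Integer seed.
#' @return A tibble with columns `gene_id`, `direction`.
#' @export
generate_stress_genes <- function(catalog, n_seeds, modules = NULL, seed = 1L) {
  catalog <- validate_catalog(catalog)
  with_seed(derive_seed(seed, "stress_genes"), {
    pool <- catalog$protein_id
    if (!is.null(modules)) {
      pool <- c(modules$protein_id, setdiff(pool, modules$protein_id))
    }
    picked <- pool[seq_len(min(n_seeds, length(pool)))]
    tibble(
      gene_id = picked,
      direction = sample(c("induced", "repressed"), length(picked), replace = TRUE)
    )
  })
}
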