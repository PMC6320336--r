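#' Monte-Carlo functional-category enrichment of protein clusters
#'
#' Tests whether clusters of proteins are enriched for functional-catalogue
#' terms by randomisation: proteins are repeatedly permuted across the
#' fixed cluster-size partition, and for every (cluster, term) pair the
#' frequency of member proteins carrying the term is recorded. A cluster is
#' enriched for a term when the observed frequency strictly exceeds the
#' 95% quantile (or `level` quantile) of the simulated frequencies.
#' Proteins annotated with several terms count towards each of them. The
#' permutation stream is keyed on sorted protein ids, so results do not
#' depend on input row order.
#'
#' @param clusters An `ap_result` over proteins, or a tibble
#'   (`protein_id`/`item_id`, `cluster`).
#' @param annotations Tibble (`protein_id`, `term_id`); every clustered
#'   protein must carry at least one term.
#' @param n_sim Number of Monte-Carlo permutations (default 10000).
#' @param level Null quantile defining enrichment (default 0.95).
#' @param seed Integer seed.
#' @return Tibble of class `egg_enrichment` (`cluster`, `term_id`,
#'   `observed`, `q_null`, `p_emp`, `enriched`, `n_sim`). `p_emp` is the
#'   add-one-corrected fraction of null frequencies at or above the
#'   observed one.
#' @export
funcat_enrichment <- function(clusters, annotations, n_sim = 10000L,
                              level = 0.95, seed = 1L) {
  cl <- if (inherits(clusters, "ap_result")) {
    tidy(clusters) %>% select(protein_id = "item_id", "cluster")
  } else if ("item_id" %in% names(clusters)) {
    clusters %>% select(protein_id = "item_id", "cluster")
  } else {
    clusters %>% select("protein_id", "cluster")
  }
  cl <- cl %>% arrange(.data$protein_id)
  unannotated <- setdiff(cl$protein_id, unique(annotations$protein_id))
  if (length(unannotated) > 0) {
    abort(sprintf("clustered protein(s) without annotation: %s",
                  paste(head(unannotated, 3), collapse = ", ")))
  }
  terms <- sort(unique(annotations$term_id))
  n <- nrow(cl)
  A <- matrix(0L, n, length(terms),
              dimnames = list(cl$protein_id, terms))
  ann <- annotations %>%
    filter(.data$protein_id %in% cl$protein_id) %>%
    distinct(.data$protein_id, .data$term_id)
  A[cbind(match(ann$protein_id, cl$protein_id),
          match(ann$term_id, terms))] <- 1L

  labels <- cl$cluster
  obs_mat <- rowsum(A, labels)
  k_ids <- rownames(obs_mat)
  nk <- nrow(obs_mat)
  nt <- length(terms)

  null <- array(0L, c(n_sim, nk, nt))
  withr::with_seed(seed, {
    for (b in seq_len(n_sim)) {
      null[b, , ] <- rowsum(A[sample.int(n), , drop = FALSE], labels)
    }
  })
  q_null <- matrix(0, nk, nt)
  p_emp <- matrix(0, nk, nt)
  for (i in seq_len(nk)) {
    for (j in seq_len(nt)) {
      nl <- null[, i, j]
      q_null[i, j] <- quantile(nl, level, type = 7)
      p_emp[i, j] <- (sum(nl >= obs_mat[i, j]) + 1) / (n_sim + 1)
    }
  }
  out <- tibble(
    cluster = utils::type.convert(rep(k_ids, nt), as.is = TRUE),
    term_id = rep(terms, each = nk),
    observed = as.vector(obs_mat),
    q_null = as.vector(q_null),
    p_emp = as.vector(p_emp),
    enriched = as.vector(obs_mat) > as.vector(q_null),
    n_sim = n_sim
  ) %>% arrange(.data$cluster, .data$term_id)
  class(out) <- c("egg_enrichment", class(out))
  out
}

#' Boolean enrichment matrix
#'
#' Reshapes an enrichment result into a cluster x term logical matrix
#' (the black-rectangle overview plot's data).
#' @param enrichment Result of [funcat_enrichment()].
#' @return Tibble, one row per cluster, one logical column per term.
#' @export
enrichment_matrix <- function(enrichment) {
  enrichment %>%
    select("cluster", "term_id", "enriched") %>%
    tidyr::pivot_wider(names_from = "term_id", values_from = "enriched")
}
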