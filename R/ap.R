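#' Pearson similarity matrix for clustering
#'
#' Builds the similarity matrix driving affinity propagation: pairwise
#' Pearson correlations between item profiles (rows), typically
#' log-transformed protein concentrations across samples. The diagonal is
#' left at `NA`; [ap_cluster()] fills it from its preference quantile.
#'
#' @param profiles Numeric matrix, one row per item, one column per
#'   observation (>= 3 observations). Rownames become item ids.
#' @return A symmetric similarity matrix with `NA` diagonal.
#' @export
build_similarity <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2) abort("need at least 2 items")
  if (ncol(profiles) < 3) abort("need at least 3 observations per item")
  sds <- apply(profiles, 1, sd)
  if (any(sds == 0 | !is.finite(sds))) {
    bad <- rownames(profiles)[which(sds == 0 | !is.finite(sds))[1]] %||%
      which(sds == 0)[1]
    abort(sprintf("zero-variance item: %s", bad))
  }
  s <- cor(t(profiles))
  diag(s) <- NA_real_
  s
}

#' Affinity propagation clustering
#'
#' Exemplar-based clustering by message passing. Responsibilities and
#' availabilities are iterated from the similarity matrix:
#' `r(i,k) <- s(i,k) - max_{k' != k} [a(i,k') + s(i,k')]`,
#' `a(i,k) <- min(0, r(k,k) + sum_{i' not in {i,k}} max(0, r(i',k)))` for
#' `i != k` and `a(k,k) <- sum_{i' != k} max(0, r(i',k))`, with damping.
#' Points whose `r(k,k) + a(k,k)` is positive become exemplars; every other
#' point joins the exemplar it is most similar to. The shared preference
#' (diagonal of the similarity matrix) is the `q`-quantile of the
#' off-diagonal similarities — `q = 0` uses the minimum, which yields a
#' conservative (small) number of clusters. Tiny seeded symmetric noise
#' breaks exact ties.
#'
#' @param s Similarity matrix (e.g. from [build_similarity()], or negative
#'   squared distances); larger = more similar. The diagonal is ignored.
#' @param q Preference quantile in `[0, 1]` (default 0).
#' @param damping Message damping factor `lambda` in `[0.5, 1)`.
#' @param max_iter Maximum iterations.
#' @param conv_iter Stop once the exemplar set has been stable this many
#'   iterations.
#' @param preference Optional explicit preference value(s) overriding `q`.
#' @param tie_seed Seed for the tie-breaking noise.
#' @return An object of class `ap_result`: exemplar per item, integer
#'   `labels`, number of clusters `k`, message matrices `responsibility`
#'   and `availability`, `iterations`, `converged`, and `net_similarity`
#'   (sum of similarities to exemplars plus exemplar preferences).
#' @examples
#' x <- c(0, 0.1, 5, 5.1)
#' s <- -outer(x, x, function(a, b) (a - b)^2)
#' ap_cluster(s, q = 0.5)$k # 2
#' @export
ap_cluster <- function(s, q = 0, damping = 0.9, max_iter = 1000L,
                       conv_iter = 100L, preference = NULL,
                       tie_seed = 42L) {
  s <- as.matrix(s)
  n <- nrow(s)
  if (n == 0) abort("empty similarity matrix")
  ids <- rownames(s) %||% as.character(seq_len(n))
  if (n == 1) {
    return(new_ap_result(exemplar = 1L, labels = 1L, k = 1L,
                         r = matrix(0, 1, 1), a = matrix(0, 1, 1),
                         iterations = 0L, converged = TRUE,
                         net_similarity = 0, ids = ids, s = s))
  }
  if (q < 0 || q > 1) abort("`q` must lie in [0, 1]")
  off <- s[row(s) != col(s)]
  if (any(!is.finite(off))) abort("similarities must be finite off-diagonal")
  pref <- preference %||% unname(quantile(off, q, type = 7))
  diag(s) <- pref

  # seeded tie-breaking noise, tiny relative to the similarity scale;
  # the caller's RNG stream is left untouched
  scale <- max(abs(off), abs(pref), 1e-300)
  noise <- withr::with_seed(tie_seed, matrix(rnorm(n * n), n, n))
  s <- s + noise * 1e-12 * scale

  r <- matrix(0, n, n)
  a <- matrix(0, n, n)
  lam <- damping
  stable <- 0L
  exemplars_old <- integer(0)
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    # responsibilities
    as_ <- a + s
    max1_idx <- max.col(as_, ties.method = "first")
    max1 <- as_[cbind(seq_len(n), max1_idx)]
    as2 <- as_
    as2[cbind(seq_len(n), max1_idx)] <- -Inf
    max2 <- apply(as2, 1, max)
    rn <- s - max1
    rn[cbind(seq_len(n), max1_idx)] <- s[cbind(seq_len(n), max1_idx)] - max2
    r <- lam * r + (1 - lam) * rn
    # availabilities
    rp <- pmax(r, 0)
    diag(rp) <- diag(r)
    cs <- colSums(rp)
    an <- matrix(cs, n, n, byrow = TRUE) - rp
    da <- diag(an)
    an <- pmin(an, 0)
    diag(an) <- da
    a <- lam * a + (1 - lam) * an
    exemplars <- which(diag(r) + diag(a) > 0)
    if (identical(exemplars, exemplars_old) && length(exemplars) > 0) {
      stable <- stable + 1L
      if (stable >= conv_iter) break
    } else {
      stable <- 0L
      exemplars_old <- exemplars
    }
  }
  converged <- stable >= conv_iter
  if (!converged) {
    warn(sprintf("affinity propagation did not converge in %d iterations",
                 max_iter))
  }
  exemplars <- which(diag(r) + diag(a) > 0)
  if (length(exemplars) == 0) {
    exemplars <- which.max(diag(r) + diag(a))
  }
  assign_to <- exemplars[max.col(s[, exemplars, drop = FALSE],
                                 ties.method = "first")]
  assign_to[exemplars] <- exemplars
  # refine: within each cluster, the best exemplar maximises the summed
  # within-cluster similarity (standard final step of the algorithm)
  for (e in unique(assign_to)) {
    members <- which(assign_to == e)
    if (length(members) > 1) {
      within <- s[members, members, drop = FALSE]
      diag(within) <- pref
      best <- members[which.max(colSums(within))]
      assign_to[members] <- best
    }
  }
  exemplars <- sort(unique(assign_to))
  labels <- match(assign_to, exemplars)
  net <- net_similarity_of(s, pref, exemplars, assign_to)
  new_ap_result(exemplar = assign_to, labels = labels,
                k = length(exemplars), r = r, a = a, iterations = it,
                converged = converged, net_similarity = net, ids = ids,
                s = s)
}

net_similarity_of <- function(s, pref, exemplars, assign_to) {
  n <- nrow(s)
  non_ex <- setdiff(seq_len(n), exemplars)
  sum(s[cbind(non_ex, assign_to[non_ex])]) + length(exemplars) * pref
}

new_ap_result <- function(exemplar, labels, k, r, a, iterations, converged,
                          net_similarity, ids, s) {
  structure(list(exemplar = exemplar, labels = labels, k = k,
                 responsibility = r, availability = a,
                 iterations = iterations, converged = converged,
                 net_similarity = net_similarity, ids = ids),
            class = "ap_result")
}

#' @export
print.ap_result <- function(x, ...) {
  cat(sprintf("<ap_result> %d items in %d cluster(s); %d iterations%s\n",
              length(x$labels), x$k, x$iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @describeIn ap_cluster One row per item: id, cluster label, exemplar
#'   flag.
#' @param x An `ap_result`.
#' @param ... Unused.
#' @method tidy ap_result
#' @export
tidy.ap_result <- function(x, ...) {
  tibble(item_id = x$ids,
         cluster = x$labels,
         exemplar = seq_along(x$labels) == x$exemplar,
         exemplar_id = x$ids[x$exemplar])
}

#' @describeIn ap_cluster One-row summary: clusters, iterations,
#'   convergence, net similarity.
#' @method glance ap_result
#' @export
glance.ap_result <- function(x, ...) {
  tibble(n_items = length(x$labels), k = x$k,
         iterations = x$iterations, converged = x$converged,
         net_similarity = x$net_similarity)
}

#' Exhaustive exemplar-set search (small instances)
#'
#' Enumerates every non-empty exemplar subset and returns the one
#' maximising the net similarity (each point assigned to its most similar
#' exemplar; exemplars contribute the preference). Exponential in n —
#' intended as an independent check of [ap_cluster()] on toy problems.
#'
#' @inheritParams ap_cluster
#' @return List with `exemplars`, `net_similarity`, `k`.
#' @export
ap_exhaustive <- function(s, q = 0, preference = NULL) {
  s <- as.matrix(s)
  n <- nrow(s)
  if (n > 14) abort("exhaustive search is limited to n <= 14")
  off <- s[row(s) != col(s)]
  pref <- preference %||% unname(quantile(off, q, type = 7))
  best <- NULL
  best_net <- -Inf
  for (mask in seq_len(2^n - 1)) {
    ex <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    sub <- s[, ex, drop = FALSE]
    assign_idx <- ex[max.col(sub, ties.method = "first")]
    assign_idx[ex] <- ex
    net <- net_similarity_of(s, pref, ex, assign_idx)
    if (net > best_net) {
      best_net <- net
      best <- ex
    }
  }
  list(exemplars = best, net_similarity = best_net, k = length(best))
}

#' Per-egg protein-cluster concentration sums
#'
#' Aggregates replicate-level protein concentrations over the members of
#' each cluster: the sum over member proteins is computed within each
#' replicate run first and then averaged across a sample's replicates.
#'
#' @param ap An `ap_result` from clustering proteins (item ids must be
#'   protein ids), or a tibble (`item_id`, `cluster`).
#' @param conc Replicate-level concentration tibble
#'   ([estimate_concentration()]).
#' @return Tibble (`sample_id`, `cluster`, `cluster_concentration`).
#' @export
summarize_clusters <- function(ap, conc) {
  members <- if (inherits(ap, "ap_result")) {
    tidy(ap) %>% select(protein_id = "item_id", "cluster")
  } else {
    ap %>% rename(protein_id = "item_id")
  }
  missing <- setdiff(members$protein_id, unique(conc$protein_id))
  if (length(missing) > 0) {
    abort(sprintf("clustered protein(s) missing from the concentration table: %s",
                  paste(head(missing, 3), collapse = ", ")))
  }
  conc %>%
    inner_join(members, by = "protein_id") %>%
    group_by(.data$cluster, .data$sample_id, .data$replicate_id) %>%
    summarise(rep_sum = sum(.data$concentration), .groups = "drop") %>%
    group_by(.data$cluster, .data$sample_id) %>%
    summarise(cluster_concentration = mean(.data$rep_sum),
              .groups = "drop") %>%
    select("sample_id", "cluster", "cluster_concentration")
}

#' Cluster eggs on composition features
#'
#' Builds one feature vector per egg (protein-cluster concentration sums
#' for both compartments, yolk lipid concentration, total carotenoid
#' concentration, egg weight), 2-SD-standardises every feature, computes
#' pairwise Pearson correlations between egg feature vectors and runs
#' affinity propagation with `q = 0`. Eggs with incomplete features are
#' dropped with a message.
#'
#' @param features Tibble with `egg_id` and one numeric column per feature.
#' @param q,damping,max_iter,conv_iter Passed to [ap_cluster()].
#' @param metric `"pearson"` (default) or `"neg_sq_euclidean"`.
#' @return An `ap_result` whose ids are egg ids.
#' @export
cluster_eggs <- function(features, q = 0, damping = 0.9,
                         max_iter = 1000L, conv_iter = 100L,
                         metric = c("pearson", "neg_sq_euclidean")) {
  metric <- match.arg(metric)
  stopifnot("egg_id" %in% names(features))
  complete <- stats::complete.cases(features)
  if (any(!complete)) {
    inform(sprintf("dropping %d egg(s) with incomplete features",
                   sum(!complete)))
    features <- features[complete, ]
  }
  if (nrow(features) < 3) abort("need >= 3 eggs with complete features")
  m <- as.matrix(features %>% select(-"egg_id"))
  rownames(m) <- features$egg_id
  keep <- apply(m, 2, function(col) sd(col) > 0)
  m <- m[, keep, drop = FALSE]
  if (ncol(m) == 0) {
    # all eggs identical on every feature: one cluster by construction
    n <- nrow(features)
    return(new_ap_result(exemplar = rep(1L, n), labels = rep(1L, n),
                         k = 1L, r = matrix(0, n, n), a = matrix(0, n, n),
                         iterations = 0L, converged = TRUE,
                         net_similarity = 0, ids = features$egg_id,
                         s = NULL))
  }
  m <- apply(m, 2, standardize_2sd)
  s <- if (metric == "pearson") {
    build_similarity(m)
  } else {
    d <- as.matrix(stats::dist(m))^2
    diag(d) <- NA
    -d
  }
  ap_cluster(s, q = q, damping = damping, max_iter = max_iter,
             conv_iter = conv_iter)
}
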