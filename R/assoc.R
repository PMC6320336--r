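#' Categorise a life-history predictor
#'
#' Applies the study's categorisation scheme: laying order into early
#' (eggs 1 and 3), middle (5 and 7) and late (9, 11 and 13); clutch size
#' into small (8-10), average (11-12) and large (13-15); lay date into
#' half-open 4-day bins from the season start (early/middle/late). Binary
#' variables pass through unchanged. Values not covered by a bin raise an
#' error that lists them; callers wanting wider bins must supply them
#' explicitly.
#'
#' @param values Vector to categorise.
#' @param variable One of `"laying_order"`, `"clutch_size"`, `"lay_date"`,
#'   or `"binary"` (pass-through).
#' @param season_start Origin of the 4-day lay-date bins (defaults to the
#'   minimum observed value).
#' @param bins Optional named list of value vectors overriding the scheme
#'   for discrete variables, e.g. `list(small = 7:10, average = 11:12,
#'   large = 13:15)`.
#' @return Character vector of category labels.
#' @examples
#' categorize(c(1, 5, 9), "laying_order") # early, middle, late
#' @export
categorize <- function(values,
                       variable = c("laying_order", "clutch_size",
                                    "lay_date", "binary"),
                       season_start = NULL, bins = NULL) {
  variable <- match.arg(variable)
  if (variable == "binary") return(as.character(values))
  if (variable == "lay_date") {
    start <- season_start %||% min(values, na.rm = TRUE)
    idx <- floor((values - start) / 4)
    labels <- c("early", "middle", "late")
    bad <- values[!is.na(idx) & (idx < 0 | idx > 2)]
    if (length(bad) > 0) {
      abort(sprintf("lay date(s) outside the three 4-day bins: %s",
                    paste(unique(bad), collapse = ", ")))
    }
    return(labels[idx + 1])
  }
  scheme <- bins %||% switch(variable,
    laying_order = list(early = c(1, 3), middle = c(5, 7),
                        late = c(9, 11, 13)),
    clutch_size = list(small = 8:10, average = 11:12, large = 13:15))
  lookup <- stats::setNames(
    rep(names(scheme), lengths(scheme)), unlist(scheme))
  out <- lookup[as.character(values)]
  if (anyNA(out[!is.na(values)])) {
    bad <- unique(values[is.na(out) & !is.na(values)])
    abort(sprintf("value(s) not covered by the %s bins: %s",
                  variable, paste(bad, collapse = ", ")))
  }
  unname(out)
}

#' Functional chi-square test of directed categorical association
#'
#' Tests whether the column variable of a contingency table is a (noisy)
#' function of the row variable. The statistic sums, per row, the
#' chi-square deviation of the row's column distribution from uniform and
#' subtracts the deviation of the pooled column margin from uniform:
#' \deqn{FC = \sum_{ij} (n_{ij} - n_{i.}/c)^2 / (n_{i.}/c) -
#'       \sum_j (n_{.j} - n/c)^2 / (n/c)}
#' referred to a chi-square distribution on (r-1)(c-1) degrees of freedom.
#' Unlike Pearson's test it is directional: FC(X -> Y) generally differs
#' from FC(Y -> X). A permutation p-value conditioning on both margins
#' (equivalent to permuting the column labels across observations) is
#' returned alongside the asymptotic one.
#'
#' @param tab Integer matrix or table of counts (rows = predictor
#'   categories, columns = outcome categories).
#' @param n_perm Number of permutation tables (0 disables the permutation
#'   p-value).
#' @param seed Seed for the permutation null.
#' @return Tibble (`statistic`, `df`, `p_asym`, `p_perm`, `n_perm`).
#' @export
functional_chisq <- function(tab, n_perm = 10000L, seed = 1L) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2) abort("need an r x c table, r,c >= 2")
  if (any(tab < 0) || any(tab != round(tab))) {
    abort("counts must be nonnegative integers")
  }
  if (any(rowSums(tab) == 0)) abort("empty row in contingency table")
  stat <- fc_statistic(tab)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  p_asym <- pchisq(stat, df, lower.tail = FALSE)
  p_perm <- NA_real_
  if (n_perm > 0) {
    sims <- withr::with_seed(
      seed, r2dtable(n_perm, rowSums(tab), colSums(tab)))
    fc_null <- vapply(sims, fc_statistic, numeric(1))
    p_perm <- (sum(fc_null >= stat - 1e-12) + 1) / (n_perm + 1)
  }
  tibble(statistic = stat, df = df, p_asym = p_asym,
         p_perm = p_perm, n_perm = n_perm)
}

fc_statistic <- function(tab) {
  c_ <- ncol(tab)
  ri <- rowSums(tab)
  cj <- colSums(tab)
  n <- sum(tab)
  e_row <- ri / c_
  term1 <- sum((tab - e_row)^2 / e_row)
  term2 <- sum((cj - n / c_)^2 / (n / c_))
  term1 - term2
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact hypergeometric test with the conventional two-sided rule: the
#' p-value sums the probabilities of all tables (with the observed
#' margins) no more probable than the observed one.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return The two-sided p-value. An empty margin returns 1 with a
#'   warning.
#' @examples
#' fisher_exact(matrix(c(13, 0, 24, 71), 2)) # < 0.001
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0),
            all(tab == round(tab)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warn("empty margin: Fisher exact p = 1")
    return(1)
  }
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' Association between egg clusters and life-history predictors
#'
#' Categorises each predictor (clutch size, lay date, laying order, female
#' age, embryo sex, paternity), cross-tabulates it against the egg cluster
#' labels, runs one functional chi-square per predictor (cluster as the
#' putative function of the predictor) and applies Benjamini-Hochberg FDR
#' across the tests. Predictors constant across the clustered eggs are
#' excluded with a warning; eggs with unknown paternity are dropped from
#' the paternity test only.
#'
#' @param egg_clusters Tibble (`egg_id`, `cluster`) or an `ap_result`
#'   over eggs.
#' @param design Egg design tibble ([simulate_design()]).
#' @param predictors Predictor subset to test.
#' @param n_perm,seed Passed to [functional_chisq()].
#' @return Tibble (`predictor`, `statistic`, `df`, `p_asym`, `p_perm`,
#'   `p_fdr`), FDR computed on the asymptotic p-values.
#' @export
egg_cluster_association <- function(egg_clusters, design,
                                    predictors = c("clutch_size",
                                                   "lay_date",
                                                   "laying_order",
                                                   "female_age",
                                                   "embryo_sex",
                                                   "paternity"),
                                    n_perm = 10000L, seed = 1L) {
  cl <- if (inherits(egg_clusters, "ap_result")) {
    tidy(egg_clusters) %>% select(egg_id = "item_id", "cluster")
  } else {
    egg_clusters %>% select("egg_id", "cluster")
  }
  df <- design %>% inner_join(cl, by = "egg_id")
  res <- purrr::map_dfr(predictors, function(p) {
    x <- df[[p]]
    keep <- rep(TRUE, nrow(df))
    if (p == "paternity") keep <- x != "unknown"
    cats <- switch(p,
      laying_order = categorize(x[keep], "laying_order"),
      clutch_size = categorize(x[keep], "clutch_size"),
      lay_date = categorize(x[keep], "lay_date"),
      as.character(x[keep]))
    if (n_distinct(cats) < 2) {
      warn(sprintf("predictor %s is constant; excluded", p))
      return(tibble())
    }
    tab <- table(cats, df$cluster[keep])
    functional_chisq(tab, n_perm = n_perm, seed = seed) %>%
      mutate(predictor = p, .before = 1)
  })
  res %>% mutate(p_fdr = p.adjust(.data$p_asym, method = "BH"))
}

#' Paternity by laying-position contingency table
#'
#' Cross-tabulates paternity (extra-pair vs within-pair) against laying
#' position (first-laid vs later) among paternity-assigned eggs — the
#' table behind the observation that extra-pair sires occur only among
#' first-laid eggs.
#'
#' @param design Egg design tibble.
#' @return 2x2 integer matrix (rows EP/WP, columns first/later).
#' @export
paternity_position_table <- function(design) {
  d <- design %>% filter(.data$paternity != "unknown")
  m <- matrix(c(
    sum(d$paternity == "extra-pair" & d$laying_order == 1),
    sum(d$paternity == "within-pair" & d$laying_order == 1),
    sum(d$paternity == "extra-pair" & d$laying_order > 1),
    sum(d$paternity == "within-pair" & d$laying_order > 1)), 2,
    dimnames = list(c("extra-pair", "within-pair"), c("first", "later")))
  m
}
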