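# small raw intensity table: one compartment, explicit replicate values
# per protein x sample; NA marks a missing (undetected) measurement
make_intensity_table <- function(values, compartment = "albumen",
                                 batch = "MS01") {
  rows <- purrr::imap_dfr(values, function(samples, prot) {
    purrr::imap_dfr(samples, function(reps, samp) {
      tibble::tibble(
        protein_id = prot, compartment = compartment, sample_id = samp,
        replicate_id = seq_along(reps), batch_id = batch,
        intensity = as.numeric(reps))
    })
  })
  attr(rows, "stage") <- "raw"
  rows
}

small_config <- function(seed = 1, ...) {
  study_config(seed = seed, n_albumen_proteins = 20, n_yolk_proteins = 15,
               ...)
}

# adjusted Rand index between two labelings (independent of the package)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# exact two-sided Fisher p by explicit hypergeometric enumeration,
# independent of stats::fisher.test
fisher_enumerate <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(a) {
    choose(r1, a) * choose(r2, c1 - a) / choose(n, c1)
  }, numeric(1))
  p_obs <- probs[tab[1, 1] - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
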