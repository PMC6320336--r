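#' Ground-truth effects for a synthetic proteome
#'
#' Draws the per-protein generative parameters that the downstream models
#' try to recover: fixed-effect coefficients of the life-history predictors
#' on the log-intensity scale, variance components (female random intercept,
#' laying-order random slope, MS batch, replicate noise) and the
#' missing-not-at-random model (logistic in log intensity). A configurable
#' fraction of proteins carries each effect; the rest have coefficient 0.
#'
#' @param config A [study_config()].
#' @param frac_affected Fraction of proteins carrying a non-zero coefficient
#'   for each predictor.
#' @param effect_sd Named numeric: SD of the non-zero coefficients, on the
#'   natural-log intensity scale (per unit of the raw covariate).
#' @param baseline_log_mean,baseline_log_sd Mean and SD of protein baseline
#'   log intensities. The default SD (2.3) spans roughly six orders of
#'   magnitude across proteins, as label-free egg proteomes do.
#' @param female_sd,order_slope_sd,batch_sd,replicate_sd Random-effect SDs
#'   on the log scale.
#' @return A list of class `ground_truth` with elements `coefficients`
#'   (tibble, one row per protein), `variance`, `missingness` and the seed.
#' @export
ground_truth <- function(config = study_config(),
                         frac_affected = 0.25,
                         effect_sd = c(laying_order = 0.05,
                                       female_age = 0.30,
                                       lay_date = 0.02,
                                       clutch_size = 0.05,
                                       embryo_sex = 0.15,
                                       paternity = 0.20),
                         baseline_log_mean = log(1e6),
                         baseline_log_sd = 2.3,
                         female_sd = 0.30,
                         order_slope_sd = 0.03,
                         batch_sd = 0.20,
                         replicate_sd = 0.25) {
  stopifnot(inherits(config, "study_config"))
  stopifnot(female_sd >= 0, order_slope_sd >= 0, batch_sd >= 0,
            replicate_sd >= 0)
  set.seed(config$seed + 101L)
  proteins <- tibble(
    protein_id = c(sprintf("ALB%03d", seq_len(config$n_albumen_proteins)),
                   sprintf("YOLK%03d", seq_len(config$n_yolk_proteins))),
    compartment = rep(c("albumen", "yolk"),
                      c(config$n_albumen_proteins, config$n_yolk_proteins))
  )
  np <- nrow(proteins)
  draw <- function(sd) {
    hit <- runif(np) < frac_affected
    if_else(hit, rnorm(np, 0, sd), 0)
  }
  coefs <- proteins %>%
    mutate(
      baseline = rnorm(np, baseline_log_mean, baseline_log_sd),
      b_laying_order = draw(effect_sd[["laying_order"]]),
      b_female_age = draw(effect_sd[["female_age"]]),
      b_lay_date = draw(effect_sd[["lay_date"]]),
      b_clutch_size = draw(effect_sd[["clutch_size"]]),
      b_embryo_sex = draw(effect_sd[["embryo_sex"]]),
      b_paternity = draw(effect_sd[["paternity"]])
    )
  structure(
    list(coefficients = coefs,
         variance = c(female_sd = female_sd,
                      order_slope_sd = order_slope_sd,
                      batch_sd = batch_sd,
                      replicate_sd = replicate_sd),
         missingness = c(rate = config$missing_rate,
                         slope = config$missing_slope),
         seed = config$seed),
    class = "ground_truth")
}

#' Null ground truth (all effects and variance components zero)
#'
#' Degenerate generative parameters useful for type-I-error checks: every
#' replicate intensity equals the protein baseline exactly and nothing is
#' missing.
#' @inheritParams ground_truth
#' @export
null_ground_truth <- function(config = study_config()) {
  gt <- ground_truth(config,
                     frac_affected = 0,
                     female_sd = 0, order_slope_sd = 0,
                     batch_sd = 0, replicate_sd = 0)
  gt$missingness["rate"] <- 0
  gt
}

#' Simulate a replicate-level label-free proteome
#'
#' Generates log-normal intensities following a linear model on the log
#' scale (protein baseline + fixed effects x covariates + per-female random
#' intercept + laying-order random slope + MS-batch effect + replicate
#' noise), applies intensity-dependent missingness (logistic in log
#' intensity, calibrated so the overall missing fraction matches the
#' configured rate), and annotates each protein with 1 to
#' `config$max_terms_per_protein` of the `config$n_funcat_terms` first-level
#' functional-catalogue terms.
#'
#' Covariates are centred before multiplying by the ground-truth
#' coefficients so that the protein baseline stays the mid-design intensity.
#'
#' @param design Egg design tibble from [simulate_design()].
#' @param truth A [ground_truth()] whose protein set matches `config`.
#' @param config The [study_config()] used for `design`.
#' @return A list with `intensities` (tibble: `protein_id`, `compartment`,
#'   `sample_id`, `replicate_id`, `batch_id`, `intensity`; `NA` = missing,
#'   stage attribute `"raw"`) and `annotations` (tibble: `protein_id`,
#'   `term_id`).
#' @export
simulate_proteome <- function(design, truth, config = study_config()) {
  stopifnot(inherits(truth, "ground_truth"), nrow(design) > 0)
  coefs <- truth$coefficients
  if (nrow(coefs) != config$n_albumen_proteins + config$n_yolk_proteins) {
    abort("ground truth protein count does not match `config`.")
  }
  set.seed(config$seed + 202L)

  n_eggs <- nrow(design)
  # technical replicates and randomised-block batch assignment per sample
  reps <- sample(seq(config$replicates_per_sample[1],
                     config$replicates_per_sample[2]),
                 n_eggs, replace = TRUE)
  runs <- design %>%
    select("egg_id") %>%
    mutate(n_rep = reps) %>%
    tidyr::uncount(.data$n_rep, .id = "replicate_id") %>%
    mutate(batch_id = NA_character_)
  # randomised block: shuffle run order, then deal batches round-robin
  perm <- sample.int(nrow(runs))
  runs$batch_id[perm] <- sprintf(
    "MS%02d", (seq_len(nrow(runs)) %% config$n_ms_batches) + 1L)

  # centred covariates
  x_order <- design$laying_order - mean(design$laying_order)
  x_age <- (design$female_age == "adult") - mean(design$female_age == "adult")
  x_date <- design$lay_date - mean(design$lay_date)
  x_clutch <- design$clutch_size - mean(design$clutch_size)
  x_sex <- (design$embryo_sex == "male") - mean(design$embryo_sex == "male")
  x_pat <- as.numeric(design$paternity == "extra-pair")
  x_pat <- x_pat - mean(x_pat)

  np <- nrow(coefs)
  females <- unique(design$female_id)
  vc <- truth$variance
  u_female <- matrix(rnorm(np * length(females), 0, vc[["female_sd"]]),
                     np, dimnames = list(coefs$protein_id, females))
  u_slope <- matrix(rnorm(np * length(females), 0, vc[["order_slope_sd"]]),
                    np, dimnames = list(coefs$protein_id, females))
  batches <- sort(unique(runs$batch_id))
  u_batch <- matrix(rnorm(np * length(batches), 0, vc[["batch_sd"]]),
                    np, dimnames = list(coefs$protein_id, batches))

  fi <- match(design$female_id, females)
  # protein x egg matrix of expected log intensities
  mu <- coefs$baseline +
    outer(coefs$b_laying_order, x_order) +
    outer(coefs$b_female_age, x_age) +
    outer(coefs$b_lay_date, x_date) +
    outer(coefs$b_clutch_size, x_clutch) +
    outer(coefs$b_embryo_sex, x_sex) +
    outer(coefs$b_paternity, x_pat) +
    u_female[, fi, drop = FALSE] +
    u_slope[, fi, drop = FALSE] *
      matrix(x_order, np, n_eggs, byrow = TRUE)

  tab <- tidyr::crossing(protein_id = coefs$protein_id,
                         runs %>% rename(sample_id = "egg_id")) %>%
    left_join(coefs %>% select("protein_id", "compartment"),
              by = "protein_id")
  pi_ <- match(tab$protein_id, coefs$protein_id)
  ei <- match(tab$sample_id, design$egg_id)
  log_int <- mu[cbind(pi_, ei)] +
    u_batch[cbind(pi_, match(tab$batch_id, batches))] +
    rnorm(nrow(tab), 0, vc[["replicate_sd"]])

  # MNAR: logistic missingness on standardised log intensity, with the
  # intercept calibrated so the realised overall rate hits the target
  rate <- truth$missingness[["rate"]]
  if (rate > 0) {
    z <- (log_int - mean(log_int)) / sd(log_int)
    slope <- truth$missingness[["slope"]]
    a <- tryCatch(
      stats::uniroot(function(a) mean(plogis(a + slope * z)) - rate,
                     c(-20, 20))$root,
      error = function(e) qlogis(rate))
    miss <- runif(nrow(tab)) < plogis(a + slope * z)
  } else {
    miss <- rep(FALSE, nrow(tab))
  }
  intensity <- exp(log_int)
  intensity[miss] <- NA_real_

  intensities <- tab %>%
    mutate(intensity = intensity) %>%
    select("protein_id", "compartment", "sample_id", "replicate_id",
           "batch_id", "intensity") %>%
    arrange(.data$protein_id, .data$sample_id, .data$replicate_id)
  attr(intensities, "stage") <- "raw"

  n_terms <- pmin(1L + rbinom(np, config$max_terms_per_protein - 1L, 0.12),
                  config$max_terms_per_protein)
  terms <- sprintf("FC%02d", seq_len(config$n_funcat_terms))
  annotations <- tibble(protein_id = coefs$protein_id, k = n_terms) %>%
    mutate(term_id = purrr::map(.data$k, ~ sample(terms, .x))) %>%
    select(-"k") %>%
    tidyr::unnest("term_id")

  list(intensities = intensities, annotations = annotations)
}
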