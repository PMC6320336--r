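#' Reference carotenoid panel of the synthetic yolk
#'
#' Species means, coefficients of variation and detection fractions used as
#' generator targets (micrograms per gram wet yolk). The sum of the panel
#' means, weighting the intermittently detected species by its detection
#' fraction, reproduces the study-scale total of ~45.8 ug/g. The `loading`
#' column sets each species' correlation with the shared dietary latent
#' factor: the major xanthophylls (lutein, zeaxanthin) track it tightly,
#' the minor carotenes more loosely, so inter-species correlations are all
#' positive but heterogeneous.
#' @return A tibble with columns `species`, `mean_ugg`, `cv_pct`,
#'   `presence`, `loading`.
#' @export
carotenoid_panel <- function() {
  tibble(
    species = c("lutein", "zeaxanthin", "beta-carotene", "beta-zeacarotene",
                "gamma-carotene", "gamma-carotene-Z", "unidentified"),
    mean_ugg = c(22.1, 7.2, 3.6, 3.5, 1.7, 1.2, 7.7),
    cv_pct = c(89, 87, 69, 175, 134, 92, 91),
    presence = c(1, 1, 1, 0.67, 1, 1, 1),
    loading = c(0.95, 0.93, 0.85, 0.60, 0.65, 0.70, 0.80)
  )
}

#' Simulate yolk carotenoid and lipid concentrations
#'
#' Carotenoid species are log-normal with means and CVs from
#' [carotenoid_panel()], driven by one shared latent per-egg factor (so all
#' pairwise correlations are positive, as carotenoids sourced from a common
#' diet are) that declines with laying order. One minor species
#' (beta-zeacarotene) is detected in only ~67% of eggs. Total lipids
#' (mg/g wet yolk) are log-normal around 222.1 with a laying-order decline
#' and a between-female component. HPLC batch labels are attached by
#' randomised blocks.
#'
#' @param design Egg design tibble from [simulate_design()].
#' @param config The [study_config()] used for `design`.
#' @param order_effect_carotenoid Latent-factor shift (SD units) per laying
#'   position; negative values deplete late eggs. Set to 0 for a null
#'   generator.
#' @param order_effect_lipid Lipid trend, mg/g wet yolk per laying position.
#' @param lipid_mean,lipid_cv Lipid mean (mg/g) and CV (%).
#' @param lipid_icc Between-female fraction of lipid variance.
#' @param carotenoid_icc Between-female fraction of latent-factor variance.
#' @param loading_scale Multiplier on the panel's per-species latent-factor
#'   loadings (capped at 1); 0 decouples the species.
#' @return A list with `carotenoids` (long tibble: `egg_id`, `species`,
#'   `concentration_ugg`, `hplc_batch`; `NA` = not detected) and `lipids`
#'   (tibble: `egg_id`, `lipid_mgg`, `hplc_batch`).
#' @export
simulate_yolk_chemistry <- function(design, config = study_config(),
                                    order_effect_carotenoid = -0.12,
                                    order_effect_lipid = -2.0,
                                    lipid_mean = 222.1, lipid_cv = 10,
                                    lipid_icc = 0.20,
                                    carotenoid_icc = 0.04,
                                    loading_scale = 1) {
  stopifnot(nrow(design) > 0, loading_scale >= 0)
  set.seed(config$seed + 303L)
  n <- nrow(design)
  females <- unique(design$female_id)
  fi <- match(design$female_id, females)
  x_order <- design$laying_order - mean(design$laying_order)

  u_f <- rnorm(length(females), 0, sqrt(carotenoid_icc))
  latent <- u_f[fi] + rnorm(n, 0, sqrt(1 - carotenoid_icc)) +
    order_effect_carotenoid * x_order

  batch <- rep(NA_character_, n)
  batch[sample.int(n)] <- sprintf(
    "HPLC%02d", (seq_len(n) %% config$n_hplc_batches) + 1L)

  panel <- carotenoid_panel()
  caro <- tidyr::crossing(egg_id = design$egg_id,
                          species = panel$species) %>%
    left_join(panel, by = "species")
  ei <- match(caro$egg_id, design$egg_id)
  sigma <- sqrt(log(1 + (caro$cv_pct / 100)^2))
  mu <- log(caro$mean_ugg) - sigma^2 / 2
  lam <- pmin(caro$loading * loading_scale, 1)
  logc <- mu + sigma * (lam * latent[ei] +
                          sqrt(1 - lam^2) * rnorm(nrow(caro)))
  detected <- runif(nrow(caro)) < caro$presence
  caro <- caro %>%
    mutate(concentration_ugg = if_else(detected, exp(logc), NA_real_),
           hplc_batch = batch[ei]) %>%
    select("egg_id", "species", "concentration_ugg", "hplc_batch")

  sig_l <- sqrt(log(1 + (lipid_cv / 100)^2))
  u_l <- rnorm(length(females), 0, sqrt(lipid_icc) * sig_l)
  log_lip <- log(lipid_mean) - sig_l^2 / 2 + u_l[fi] +
    rnorm(n, 0, sqrt(1 - lipid_icc) * sig_l)
  lipids <- tibble(
    egg_id = design$egg_id,
    lipid_mgg = exp(log_lip) + order_effect_lipid * x_order,
    hplc_batch = batch
  )

  list(carotenoids = caro, lipids = lipids)
}

#' Per-egg total carotenoid concentration
#'
#' Sums detected species per egg (undetected species contribute zero).
#' @param carotenoids Long carotenoid tibble from
#'   [simulate_yolk_chemistry()].
#' @return Tibble with `egg_id`, `total_carotenoid_ugg`, `hplc_batch`.
#' @export
total_carotenoids <- function(carotenoids) {
  carotenoids %>%
    group_by(.data$egg_id, .data$hplc_batch) %>%
    summarise(total_carotenoid_ugg = sum(.data$concentration_ugg,
                                         na.rm = TRUE),
              .groups = "drop") %>%
    select("egg_id", "total_carotenoid_ugg", "hplc_batch")
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper: design, ground truth, replicate-level proteome with
#' annotations, and yolk chemistry, all from one seed.
#' @param config A [study_config()].
#' @param truth Optional [ground_truth()]; drawn from `config` by default.
#' @param ... Passed to [simulate_yolk_chemistry()].
#' @return A list of class `egg_study` with elements `config`, `design`,
#'   `truth`, `intensities`, `annotations`, `carotenoids`, `lipids`.
#' @examples
#' study <- simulate_study(study_config(seed = 7))
#' nrow(study$design)
#' @export
simulate_study <- function(config = study_config(), truth = NULL, ...) {
  design <- simulate_design(config)
  truth <- truth %||% ground_truth(config)
  prot <- simulate_proteome(design, truth, config)
  chem <- simulate_yolk_chemistry(design, config, ...)
  structure(
    list(config = config, design = design, truth = truth,
         intensities = prot$intensities, annotations = prot$annotations,
         carotenoids = chem$carotenoids, lipids = chem$lipids),
    class = "egg_study")
}

#' @export
print.egg_study <- function(x, ...) {
  cat("<egg_study>\n")
  cat("  eggs:", nrow(x$design), "from",
      n_distinct(x$design$female_id), "clutches\n")
  cat("  intensities:", nrow(x$intensities), "replicate-level records,",
      sprintf("%.1f%% missing", 100 * mean(is.na(x$intensities$intensity))),
      "\n")
  cat("  proteins:", n_distinct(x$intensities$protein_id), "\n")
  invisible(x)
}

#' Write a synthetic study to TSV files
#'
#' Emits `metadata.tsv` (one row per egg), `intensities.tsv` (long
#' replicate-level), `annotations.tsv`, `carotenoids.tsv`, `lipids.tsv` and
#' `ground_truth.tsv` (per-protein coefficients; variance components and
#' missingness parameters are prepended as comment lines).
#' @param study An `egg_study` from [simulate_study()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "egg_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  w(study$design, "metadata.tsv")
  w(study$intensities, "intensities.tsv")
  w(study$annotations, "annotations.tsv")
  w(study$carotenoids, "carotenoids.tsv")
  w(study$lipids, "lipids.tsv")
  gt_path <- file.path(dir, "ground_truth.tsv")
  hdr <- c(
    sprintf("# variance: %s", paste(names(study$truth$variance),
                                    study$truth$variance,
                                    sep = "=", collapse = " ")),
    sprintf("# missingness: %s", paste(names(study$truth$missingness),
                                       study$truth$missingness,
                                       sep = "=", collapse = " ")))
  writeLines(hdr, gt_path)
  suppressWarnings(utils::write.table(
    study$truth$coefficients, gt_path, sep = "\t", quote = FALSE,
    row.names = FALSE, append = TRUE))
  invisible(dir)
}
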