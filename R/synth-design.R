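#' Configuration for a synthetic clutch-sampling study
#'
#' Bundles the design constants of the emulated field study: 39 first
#' clutches sampled at laying positions 1 and 9, ten of which were fully
#' sampled at every second position, giving 114 eggs in total; clutch sizes
#' of 7-15 eggs; extra-pair sires only among first-laid eggs; 1-3 technical
#' MS replicates per sample; batched MS and HPLC measurement.
#'
#' @param n_clutches Number of clutches (females) sampled.
#' @param n_full_clutches Number of clutches sampled at every second laying
#'   position (the rest contribute eggs 1 and 9 only).
#' @param clutch_size_range Integer range of clutch sizes for the
#'   partially sampled clutches. The lower bound is raised to 9 internally
#'   because those clutches must contain a 9th egg.
#' @param full_clutch_sizes Clutch sizes of the fully sampled clutches. The
#'   default multiset is calibrated so that the odd laying positions beyond
#'   eggs 1 and 9 contribute exactly 36 extra eggs, i.e. 114 eggs overall.
#' @param ep_rate_first_eggs Probability that a first-laid egg is sired by
#'   an extra-pair male. Later eggs are always within-pair. The default
#'   (13/37) yields ~12% extra-pair eggs among all paternity-assigned eggs.
#' @param n_unassigned Number of eggs with unknown paternity (one clutch's
#'   eggs plus singletons, as in field parentage data).
#' @param p_yearling Probability that a female is a yearling.
#' @param season_length Length (days) of the laying window for first eggs.
#' @param egg_weight_mean,egg_weight_sd Mean and SD of egg weight (g).
#' @param egg_weight_icc Fraction of egg-weight variance between females.
#' @param age_first_egg_diff Adult-minus-yearling weight difference (g) at
#'   laying position 1.
#' @param order_slope_yearling,order_slope_adult Within-clutch egg-weight
#'   trend (g per laying position) for yearling and adult females.
#' @param n_albumen_proteins,n_yolk_proteins Proteome sizes.
#' @param n_funcat_terms Number of first-level functional-catalogue terms.
#' @param max_terms_per_protein Maximum number of terms per protein.
#' @param replicates_per_sample Integer range of technical MS replicates.
#' @param n_ms_batches,n_hplc_batches Number of measurement batches.
#' @param missing_rate Target overall fraction of missing intensities.
#' @param missing_slope Logistic slope of missingness on centred
#'   log-intensity (negative: low-abundance values go missing more often).
#' @param seed Integer seed; fixed seeds give bit-identical datasets.
#'
#' @return A list of class `study_config`.
#' @examples
#' cfg <- study_config()
#' design <- simulate_design(cfg)
#' nrow(design) # 114
#' @export
study_config <- function(n_clutches = 39,
                         n_full_clutches = 10,
                         clutch_size_range = c(7L, 15L),
                         full_clutch_sizes = c(11L, 11L, 11L, 12L, 12L, 12L,
                                               9L, 9L, 10L, 10L),
                         ep_rate_first_eggs = 13 / 37,
                         n_unassigned = 6L,
                         p_yearling = 0.5,
                         season_length = 12L,
                         egg_weight_mean = 1.16,
                         egg_weight_sd = 0.11,
                         egg_weight_icc = 0.80,
                         age_first_egg_diff = 0.094,
                         order_slope_yearling = 0.006,
                         order_slope_adult = -0.006,
                         n_albumen_proteins = 171L,
                         n_yolk_proteins = 156L,
                         n_funcat_terms = 21L,
                         max_terms_per_protein = 16L,
                         replicates_per_sample = c(1L, 3L),
                         n_ms_batches = 4L,
                         n_hplc_batches = 3L,
                         missing_rate = 0.15,
                         missing_slope = -1.5,
                         seed = 1L) {
  if (length(clutch_size_range) != 2L ||
      clutch_size_range[1] > clutch_size_range[2]) {
    abort("`clutch_size_range` must be c(min, max) with min <= max.")
  }
  if (clutch_size_range[1] < 1 || clutch_size_range[2] > 20) {
    abort("`clutch_size_range` must lie within a plausible 1..20 window.")
  }
  if (ep_rate_first_eggs < 0 || ep_rate_first_eggs > 1) {
    abort("`ep_rate_first_eggs` must be a proportion in [0, 1].")
  }
  counts <- c(n_clutches = n_clutches, n_funcat_terms = n_funcat_terms,
              n_ms_batches = n_ms_batches, n_hplc_batches = n_hplc_batches)
  if (any(counts < 1)) {
    abort(paste0("count fields must be >= 1; offending: ",
                 paste(names(counts)[counts < 1], collapse = ", ")))
  }
  if (n_full_clutches < 0 || n_albumen_proteins < 0 || n_yolk_proteins < 0) {
    abort("counts cannot be negative")
  }
  if (n_albumen_proteins + n_yolk_proteins < 1) {
    abort("the proteome needs at least one protein")
  }
  if (n_full_clutches > n_clutches) {
    abort("`n_full_clutches` cannot exceed `n_clutches`.")
  }
  if (length(full_clutch_sizes) != n_full_clutches) {
    abort("`full_clutch_sizes` must have length `n_full_clutches`.")
  }
  if (any(full_clutch_sizes < 9)) {
    abort("fully sampled clutches must contain a 9th egg (size >= 9).")
  }
  structure(as.list(environment()), class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n")
  cat("  clutches:", x$n_clutches,
      sprintf("(%d fully sampled)", x$n_full_clutches), "\n")
  cat("  proteome:", x$n_albumen_proteins, "albumen +",
      x$n_yolk_proteins, "yolk proteins\n")
  cat("  EP rate (first eggs):", round(x$ep_rate_first_eggs, 3), "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' Simulate the egg-level sampling design
#'
#' Draws one egg record per collected egg: female identity, laying order,
#' lay date of the clutch, clutch size, female age, embryo sex, paternity
#' and the weights of the egg and its two compartments, plus total protein
#' concentration per compartment. Egg weight is generated with a
#' between-female variance fraction given by `config$egg_weight_icc` and
#' age-dependent laying-order trends (yearlings lay lighter first eggs that
#' get heavier along the clutch; adults the opposite).
#'
#' @param config A [study_config()].
#' @return A tibble with one row per egg (columns `egg_id`, `female_id`,
#'   `laying_order`, `lay_date`, `clutch_size`, `female_age`, `embryo_sex`,
#'   `paternity`, `egg_weight`, `albumen_weight`, `yolk_weight`,
#'   `albumen_protein_mgg`, `yolk_protein_mgg`).
#' @export
simulate_design <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$seed)

  n <- config$n_clutches
  nf <- config$n_full_clutches
  female_id <- sprintf("F%02d", seq_len(n))
  fully_sampled <- c(rep(TRUE, nf), rep(FALSE, n - nf))

  lo <- max(9L, config$clutch_size_range[1])
  hi <- config$clutch_size_range[2]
  clutch_size <- integer(n)
  clutch_size[fully_sampled] <- as.integer(config$full_clutch_sizes)
  clutch_size[!fully_sampled] <- sample(lo:hi, n - nf, replace = TRUE)

  female_age <- if_else(runif(n) < config$p_yearling, "yearling", "adult")
  lay_date <- sample.int(config$season_length, n, replace = TRUE) - 1L

  females <- tibble(
    female_id, fully_sampled, clutch_size, female_age, lay_date,
    u_female = rnorm(n, 0, sqrt(config$egg_weight_icc) * config$egg_weight_sd)
  )

  eggs <- females %>%
    mutate(laying_order = purrr::map2(.data$fully_sampled, .data$clutch_size,
      function(full, size) {
        if (full) seq(1L, size, by = 2L) else c(1L, 9L)
      })) %>%
    tidyr::unnest("laying_order") %>%
    select(-"fully_sampled")

  half <- config$age_first_egg_diff / 2
  slope <- if_else(eggs$female_age == "yearling",
                   config$order_slope_yearling, config$order_slope_adult)
  resid_sd <- sqrt(1 - config$egg_weight_icc) * config$egg_weight_sd

  eggs <- eggs %>%
    mutate(
      egg_id = sprintf("E%03d", row_number()),
      embryo_sex = sample(c("female", "male"), n(), replace = TRUE),
      egg_weight = config$egg_weight_mean +
        if_else(.data$female_age == "adult", half, -half) +
        slope * (.data$laying_order - 1) +
        .data$u_female + rnorm(n(), 0, resid_sd),
      # compartment fractions: ~72% albumen, ~23% yolk, remainder shell;
      # jointly rescaled if a draw would leave no shell
      .fa = rnorm(n(), 0.716, 0.020),
      .fy = rnorm(n(), 0.233, 0.015),
      .shrink = pmin(1, 0.96 / (.data$.fa + .data$.fy)),
      albumen_weight = .data$egg_weight * .data$.fa * .data$.shrink,
      yolk_weight = .data$egg_weight * .data$.fy * .data$.shrink,
      # total protein concentration (mg/g wet), rising along the clutch
      albumen_protein_mgg = pmax(rnorm(n(), 52.4 - 1.5, 3.5) +
                                   0.5 * (.data$laying_order - 1), 20),
      yolk_protein_mgg = pmax(rnorm(n(), 61.2 - 0.5, 5.0) +
                                0.2 * (.data$laying_order - 1), 25)
    ) %>%
    select(-"u_female", -".fa", -".fy", -".shrink")

  # paternity: extra-pair sires occur among first-laid eggs only; one
  # clutch plus odd singletons lack parentage assignment
  unassigned <- character(0)
  if (config$n_unassigned > 0) {
    drop_female <- sample(females$female_id[females$fully_sampled], 1)
    unassigned <- eggs$egg_id[eggs$female_id == drop_female]
    extra <- config$n_unassigned - length(unassigned)
    if (extra > 0) {
      pool <- setdiff(eggs$egg_id, unassigned)
      unassigned <- c(unassigned, sample(pool, extra))
    } else if (extra < 0) {
      unassigned <- unassigned[seq_len(config$n_unassigned)]
    }
  }
  eggs <- eggs %>%
    mutate(
      paternity = dplyr::case_when(
        .data$egg_id %in% unassigned ~ "unknown",
        .data$laying_order == 1 &
          runif(n()) < config$ep_rate_first_eggs ~ "extra-pair",
        TRUE ~ "within-pair"
      )
    ) %>%
    select("egg_id", "female_id", "laying_order", "lay_date", "clutch_size",
           "female_age", "embryo_sex", "paternity", "egg_weight",
           "albumen_weight", "yolk_weight", "albumen_protein_mgg",
           "yolk_protein_mgg")

  stopifnot(all(eggs$albumen_weight + eggs$yolk_weight < eggs$egg_weight),
            all(eggs$laying_order <= eggs$clutch_size))
  eggs
}
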