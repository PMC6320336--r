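#' Pipeline configuration
#'
#' Collects everything [run_pipeline()] needs: the synthetic-study
#' configuration (or pre-built study), stage toggles, the sub-seeds every
#' stochastic step uses (all derived from one master seed by fixed
#' offsets), clustering and enrichment settings. All seeds are explicit
#' values; nothing draws on wall-clock entropy, so a configuration is a
#' complete recipe for byte-identical reruns.
#'
#' @param study A [study_config()] (the study to simulate) or an
#'   `egg_study` from [simulate_study()].
#' @param master_seed Master seed; stage sub-seeds default to fixed
#'   offsets from it.
#' @param stages Named logical toggles: `quant`, `infer`, `cluster`,
#'   `enrich`, `assoc`.
#' @param per_protein Also fit the per-protein model battery (the slowest
#'   stage; disable for quick runs).
#' @param q,damping,max_iter,conv_iter Affinity-propagation settings.
#' @param n_sim,level Enrichment settings.
#' @param nsim_single_step Draws for the within-model single-step
#'   correction.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(study = study_config(),
                            master_seed = 1L,
                            stages = c(quant = TRUE, infer = TRUE,
                                       cluster = TRUE, enrich = TRUE,
                                       assoc = TRUE),
                            per_protein = TRUE,
                            q = 0, damping = 0.9, max_iter = 1000L,
                            conv_iter = 100L,
                            n_sim = 10000L, level = 0.95,
                            nsim_single_step = 1e5) {
  defaults <- c(quant = TRUE, infer = TRUE, cluster = TRUE,
                enrich = TRUE, assoc = TRUE)
  defaults[names(stages)] <- stages
  structure(list(
    study = study,
    master_seed = master_seed,
    seeds = list(imputation = master_seed + 11L,
                 enrichment = master_seed + 23L,
                 ap_ties = master_seed + 37L,
                 single_step = master_seed + 53L),
    stages = defaults, per_protein = per_protein,
    ap = list(q = q, damping = damping, max_iter = max_iter,
              conv_iter = conv_iter),
    enrich = list(n_sim = n_sim, level = level),
    nsim_single_step = nsim_single_step), class = "pipeline_config")
}

#' Run the egg-composition analysis end to end
#'
#' Simulates (or accepts) a study, then runs quantitation, the
#' standardised mixed-model battery, protein/carotenoid/egg clustering,
#' functional enrichment and the categorical association stage, in the
#' order the methods prescribe. Every stage draws only on the seeds in the
#' configuration, so re-running an identical configuration reproduces the
#' numeric outputs exactly.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `egg_pipeline` with elements `study`, `quant`,
#'   `variance_partition`, `composition_effects`, `carotenoid_effects`,
#'   `protein_effects`, `interaction_effects`, `protein_clusters` (per
#'   compartment), `carotenoid_clusters`, `cluster_sums`, `egg_features`,
#'   `egg_clusters`, `enrichment`, `association`, `fisher_paternity` and a
#'   run `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  study <- if (inherits(config$study, "egg_study")) config$study else
    simulate_study(config$study)
  design <- study$design
  res <- list(config = config, study = study)
  counts <- list(eggs = nrow(design),
                 females = n_distinct(design$female_id),
                 input_proteins = n_distinct(study$intensities$protein_id))
  stage_fail <- function(stage, e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)))
  }

  if (config$stages[["quant"]]) {
    res$quant <- tryCatch(
      quantify_proteome(study$intensities, design,
                        seed = config$seeds$imputation),
      error = function(e) stage_fail("quant", e))
    counts$quantitated_proteins <- sum(res$quant$kept$kept)
  }

  # egg-level response table shared by modelling and clustering
  eggdat <- design %>%
    left_join(total_carotenoids(study$carotenoids), by = "egg_id") %>%
    left_join(study$lipids %>% select("egg_id", "lipid_mgg"),
              by = "egg_id")

  if (config$stages[["infer"]]) {
    res$variance_partition <- dplyr::bind_rows(
      variance_partition(eggdat, "egg_weight"),
      variance_partition(eggdat, "albumen_protein_mgg"),
      variance_partition(eggdat, "yolk_protein_mgg"),
      variance_partition(eggdat, "lipid_mgg"),
      variance_partition(eggdat, "total_carotenoid_ugg"))

    comp_fits <- purrr::map(
      c("egg_weight", "albumen_protein_mgg", "yolk_protein_mgg",
        "lipid_mgg"),
      ~ fit_egg_lmm(eggdat, .x, model_id = .x))
    caro_tot <- fit_egg_lmm(eggdat, "total_carotenoid_ugg",
                            transform = "log",
                            batch_col = "hplc_batch",
                            model_id = "total_carotenoid_ugg")
    res$composition_effects <- adjust_pvalues(
      c(comp_fits, list(caro_tot)), family = "composition",
      nsim = config$nsim_single_step, seed = config$seeds$single_step)

    carodat <- study$carotenoids %>%
      tidyr::pivot_wider(names_from = "species",
                         values_from = "concentration_ugg") %>%
      left_join(design, by = "egg_id")
    species <- setdiff(carotenoid_panel()$species, "unidentified")
    caro_fits <- purrr::map(species, function(sp) {
      d <- carodat %>% filter(!is.na(.data[[sp]]))
      fit_egg_lmm(d, sp, transform = "log", batch_col = "hplc_batch",
                  model_id = sp)
    })
    res$carotenoid_effects <- adjust_pvalues(
      caro_fits, family = "carotenoid",
      nsim = config$nsim_single_step, seed = config$seeds$single_step)

    res$interaction_effects <- purrr::map_dfr(
      test_interactions(eggdat, "egg_weight"),
      ~ tidy(.x) %>% filter(grepl(":", .data$term)))
  }

  if (config$stages[["quant"]] && config$stages[["infer"]] &&
      config$per_protein) {
    prot_wide <- res$quant$sample_conc %>%
      tidyr::pivot_wider(id_cols = "sample_id", names_from = "protein_id",
                         values_from = "concentration") %>%
      left_join(sample_batches(study$intensities), by = "sample_id") %>%
      left_join(design, by = c(sample_id = "egg_id"))
    prot_ids <- unique(res$quant$sample_conc$protein_id)
    res$protein_effects <- fit_model_battery(
      prot_wide, prot_ids, transform = "rank", batch_col = "ms_batch",
      family = "protein", nsim = config$nsim_single_step,
      seed = config$seeds$single_step)
  }

  if (config$stages[["quant"]] && config$stages[["cluster"]]) {
    sample_conc <- res$quant$sample_conc
    res$protein_clusters <- purrr::map(
      stats::setNames(nm = c("albumen", "yolk")),
      function(comp) {
        prof <- concentration_profiles(sample_conc, comp)
        ap_cluster(build_similarity(prof), q = config$ap$q,
                   damping = config$ap$damping,
                   max_iter = config$ap$max_iter,
                   conv_iter = config$ap$conv_iter,
                   tie_seed = config$seeds$ap_ties)
      })
    caro_prof <- study$carotenoids %>%
      filter(.data$species != "unidentified") %>%
      tidyr::pivot_wider(id_cols = "species", names_from = "egg_id",
                         values_from = "concentration_ugg")
    caro_m <- log(as.matrix(caro_prof[, -1]))
    rownames(caro_m) <- caro_prof$species
    res$carotenoid_clusters <- ap_cluster(
      build_similarity_pairwise(caro_m), q = config$ap$q,
      damping = config$ap$damping, max_iter = config$ap$max_iter,
      conv_iter = config$ap$conv_iter, tie_seed = config$seeds$ap_ties)

    res$cluster_sums <- purrr::imap_dfr(
      res$protein_clusters,
      function(ap, comp) {
        summarize_clusters(ap, res$quant$replicate_conc %>%
                             filter(.data$compartment == comp)) %>%
          mutate(compartment = comp)
      })
    res$egg_features <- res$cluster_sums %>%
      mutate(feature = paste(.data$compartment, "cluster", .data$cluster,
                             sep = "_")) %>%
      tidyr::pivot_wider(id_cols = "sample_id", names_from = "feature",
                         values_from = "cluster_concentration") %>%
      rename(egg_id = "sample_id") %>%
      left_join(eggdat %>%
                  select("egg_id", "lipid_mgg", "total_carotenoid_ugg",
                         "egg_weight"),
                by = "egg_id")
    res$egg_clusters <- cluster_eggs(res$egg_features, q = config$ap$q,
                                     damping = config$ap$damping,
                                     max_iter = config$ap$max_iter,
                                     conv_iter = config$ap$conv_iter)
    counts$albumen_clusters <- res$protein_clusters$albumen$k
    counts$yolk_clusters <- res$protein_clusters$yolk$k
    counts$egg_clusters <- res$egg_clusters$k
  }

  if (config$stages[["cluster"]] && config$stages[["enrich"]] &&
      config$stages[["quant"]]) {
    res$enrichment <- purrr::imap_dfr(
      res$protein_clusters,
      function(ap, comp) {
        funcat_enrichment(ap, study$annotations,
                          n_sim = config$enrich$n_sim,
                          level = config$enrich$level,
                          seed = config$seeds$enrichment) %>%
          mutate(compartment = comp)
      })
  }

  if (config$stages[["assoc"]]) {
    res$fisher_paternity <- tibble(
      table = list(paternity_position_table(design)),
      p = fisher_exact(paternity_position_table(design)))
    if (!is.null(res$egg_clusters)) {
      res$association <- egg_cluster_association(
        res$egg_clusters, design, seed = config$master_seed)
    }
  }

  res$manifest <- tibble(key = names(counts),
                         value = unlist(counts)) %>%
    dplyr::bind_rows(tibble(
      key = paste0("seed_", names(config$seeds)),
      value = unlist(config$seeds)))
  class(res) <- "egg_pipeline"
  res
}

# modal (first) MS batch per sample, used as the per-sample batch label in
# protein-level models once replicates are collapsed
sample_batches <- function(intensities) {
  intensities %>%
    distinct(.data$sample_id, .data$replicate_id, .data$batch_id) %>%
    group_by(.data$sample_id) %>%
    summarise(ms_batch = sort(.data$batch_id)[1], .groups = "drop")
}

# protein x sample matrix of log concentrations (clipped away from zero:
# batch-adjusted estimates can brush zero for trace proteins)
concentration_profiles <- function(sample_conc, comp) {
  wide <- sample_conc %>%
    filter(.data$compartment == comp) %>%
    tidyr::pivot_wider(id_cols = "protein_id", names_from = "sample_id",
                       values_from = "concentration")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$protein_id
  log(pmax(m, 1e-12))
}

# correlation similarity tolerating missing observations (used for
# carotenoid profiles where a minor species is not detected in every egg)
build_similarity_pairwise <- function(profiles) {
  s <- suppressWarnings(cor(t(profiles), use = "pairwise.complete.obs"))
  if (any(!is.finite(s[row(s) != col(s)]))) {
    abort("insufficient pairwise overlap to correlate profiles")
  }
  diag(s) <- NA_real_
  s
}

#' @export
print.egg_pipeline <- function(x, ...) {
  cat("<egg_pipeline>\n")
  print(x$manifest, n = Inf)
  invisible(x)
}

#' Tabular report of a pipeline run
#'
#' Emits the summary tables a reader would want from the run: the
#' predictor-by-response standardised effect grid, per-protein effects
#' ranked by standardised laying-order effect (descending), variance
#' partitions, cluster memberships and sizes, the enrichment matrix and
#' the egg-cluster association tests. Missing sections (stages toggled
#' off) are skipped and noted.
#'
#' @param result An `egg_pipeline` from [run_pipeline()].
#' @param dir Optional directory; when given, every table is written as a
#'   TSV.
#' @return Named list of tibbles, invisibly when `dir` is given.
#' @export
write_report <- function(result, dir = NULL) {
  stopifnot(inherits(result, "egg_pipeline"))
  tables <- list()
  if (!is.null(result$composition_effects)) {
    tables$effects_grid <- dplyr::bind_rows(
      result$composition_effects,
      result$carotenoid_effects) %>%
      select("family", "model", "term", "estimate", "std_error",
             "conf_low", "conf_high", "statistic", "p_raw",
             "p_single_step", "p_fdr")
  }
  if (!is.null(result$protein_effects)) {
    tables$protein_ranking <- result$protein_effects %>%
      filter(.data$term == "laying_order") %>%
      arrange(dplyr::desc(.data$estimate))
    n_sig <- sum(tables$protein_ranking$p_fdr < 0.05, na.rm = TRUE)
    tables$protein_summary <- tibble(
      n_proteins = nrow(tables$protein_ranking),
      n_significant_fdr = n_sig)
  }
  if (!is.null(result$variance_partition)) {
    tables$variance_partition <- result$variance_partition
  }
  if (!is.null(result$protein_clusters)) {
    tables$protein_clusters <- purrr::imap_dfr(
      result$protein_clusters,
      ~ tidy(.x) %>% mutate(compartment = .y))
    tables$cluster_sizes <- tables$protein_clusters %>%
      count(.data$compartment, .data$cluster)
  }
  if (!is.null(result$enrichment)) {
    tables$enrichment <- as_tibble(result$enrichment)
  }
  if (!is.null(result$egg_clusters)) {
    tables$egg_clusters <- tidy(result$egg_clusters)
  }
  if (!is.null(result$association)) {
    tables$association <- result$association
  }
  if (!is.null(result$fisher_paternity)) {
    tables$fisher_paternity <- tibble(p = result$fisher_paternity$p)
  }
  missing <- setdiff(c("effects_grid", "protein_clusters", "enrichment",
                       "association"), names(tables))
  if (length(missing) > 0) {
    inform(paste("sections not available:",
                 paste(missing, collapse = ", ")))
  }
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    purrr::iwalk(tables, function(tb, nm) {
      utils::write.table(tb, file.path(dir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    })
    return(invisible(tables))
  }
  tables
}
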