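#' Replicate-level identification flags
#'
#' A protein counts as identified in a sample when it has a strictly
#' positive intensity in at least two technical replicate runs of that
#' sample. Missing values (and zeros, the usual "not detected" encoding of
#' search-engine output) never count as positive.
#'
#' @param intensities Long raw intensity tibble with columns `protein_id`,
#'   `compartment`, `sample_id`, `replicate_id`, `intensity` (`NA` =
#'   missing).
#' @return Tibble (`protein_id`, `compartment`, `sample_id`, `n_positive`,
#'   `identified`). Samples run with a single replicate can never satisfy
#'   the criterion; a warning lists them.
#' @export
flag_identified <- function(intensities) {
  check_stage(intensities, "raw")
  singles <- intensities %>%
    distinct(.data$compartment, .data$sample_id, .data$replicate_id) %>%
    count(.data$compartment, .data$sample_id) %>%
    filter(.data$n < 2)
  if (nrow(singles) > 0) {
    warn(sprintf(
      "%d sample(s) have a single replicate and cannot meet the two-replicate identification criterion (e.g. %s)",
      nrow(singles), singles$sample_id[1]))
  }
  intensities %>%
    group_by(.data$protein_id, .data$compartment, .data$sample_id) %>%
    summarise(n_positive = sum(!is.na(.data$intensity) & .data$intensity > 0),
              .groups = "drop") %>%
    mutate(identified = .data$n_positive >= 2L)
}

#' Quantitation filter across biological groups
#'
#' A protein is retained when it is identified in at least half of the
#' samples of at least one biological group (half rounded up).
#'
#' @param flags Output of [flag_identified()].
#' @param groups Tibble (`sample_id`, `group`) labelling every sample.
#' @return Tibble (`protein_id`, `compartment`, `kept`).
#' @export
filter_quantitated <- function(flags, groups) {
  stopifnot(all(c("sample_id", "group") %in% names(groups)))
  missing_lab <- setdiff(unique(flags$sample_id), groups$sample_id)
  if (length(missing_lab) > 0) {
    abort(sprintf("samples without a group label: %s",
                  paste(head(missing_lab, 3), collapse = ", ")))
  }
  sizes <- groups %>% count(.data$group, name = "n_group")
  if (any(sizes$n_group == 0)) abort("empty biological group")
  flags %>%
    left_join(groups, by = "sample_id") %>%
    left_join(sizes, by = "group") %>%
    group_by(.data$protein_id, .data$compartment, .data$group,
             .data$n_group) %>%
    summarise(n_ident = sum(.data$identified), .groups = "drop") %>%
    mutate(enough = .data$n_ident >= ceiling(.data$n_group / 2)) %>%
    group_by(.data$protein_id, .data$compartment) %>%
    summarise(kept = any(.data$enough), .groups = "drop")
}

#' Total-signal normalisation
#'
#' Divides every intensity by the summed intensity of its (compartment,
#' sample, replicate) run, so non-missing values within a run sum to one.
#'
#' @param intensities Long raw intensity tibble.
#' @return The table with `intensity` rescaled and stage `"normalized"`.
#' @export
normalize_total_signal <- function(intensities) {
  check_stage(intensities, "raw")
  out <- intensities %>%
    group_by(.data$compartment, .data$sample_id, .data$replicate_id) %>%
    mutate(.total = sum(.data$intensity, na.rm = TRUE)) %>%
    ungroup()
  bad <- out %>%
    filter(.data$.total <= 0) %>%
    distinct(.data$compartment, .data$sample_id, .data$replicate_id)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "zero total MS signal in replicate %s of sample %s (%s)",
      bad$replicate_id[1], bad$sample_id[1], bad$compartment[1]))
  }
  out <- out %>%
    mutate(intensity = .data$intensity / .data$.total) %>%
    select(-".total")
  attr(out, "stage") <- "normalized"
  out
}

#' Bounded-uniform imputation of missing intensities
#'
#' Replaces each missing normalised intensity by a draw from a uniform
#' distribution bounded by the minimum and the 1% quantile (linear
#' interpolation between order statistics) of the observed normalised
#' intensities of the same (compartment, sample, replicate) run — the
#' usual "low-abundance" treatment of intensity-dependent missingness.
#' Each run consumes its own random stream derived from `seed` and the
#' run's rank in sorted key order, so adding proteins to one run never
#' perturbs draws in another.
#'
#' @param intensities Normalised intensity tibble from
#'   [normalize_total_signal()].
#' @param seed Integer master seed.
#' @return The table with `NA` values filled in; stage `"imputed"`.
#' @export
impute_missing <- function(intensities, seed = 1L) {
  check_stage(intensities, "normalized")
  out <- intensities %>%
    arrange(.data$compartment, .data$sample_id, .data$replicate_id,
            .data$protein_id)
  key <- paste(out$compartment, out$sample_id, out$replicate_id, sep = "\r")
  groups <- split(seq_len(nrow(out)), key)
  groups <- groups[order(names(groups))]
  vals <- out$intensity
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    obs <- vals[idx][!is.na(vals[idx])]
    nas <- idx[is.na(vals[idx])]
    if (length(nas) == 0) next
    if (length(obs) == 0) {
      abort(sprintf("run %s has no observed values; imputation bounds undefined",
                    gsub("\r", "/", names(groups)[g])))
    }
    lo <- min(obs)
    hi <- unname(quantile(obs, 0.01, type = 7))
    vals[nas] <- withr::with_seed(
      (seed + g) %% .Machine$integer.max,
      runif(length(nas), lo, hi))
  }
  out$intensity <- vals
  attr(out, "stage") <- "imputed"
  out
}

#' Per-sample total protein and compartment weights from an egg design
#'
#' @param design Egg design tibble ([simulate_design()]).
#' @return Tibble (`sample_id`, `compartment`, `total_protein_mg`,
#'   `weight_g`), one row per egg and compartment.
#' @export
compartment_totals <- function(design) {
  dplyr::bind_rows(
    tibble(sample_id = design$egg_id, compartment = "albumen",
           total_protein_mg = design$albumen_protein_mgg *
             design$albumen_weight,
           weight_g = design$albumen_weight),
    tibble(sample_id = design$egg_id, compartment = "yolk",
           total_protein_mg = design$yolk_protein_mgg * design$yolk_weight,
           weight_g = design$yolk_weight)
  )
}

#' Concentration estimation from normalised intensities
#'
#' Converts each (imputed) normalised intensity into mg protein per g wet
#' compartment: intensity x total protein (mg) / compartment weight (g).
#' Imputation adds a little mass on top of the unit sum of the observed
#' normalised intensities, so each run's values are first rescaled to
#' proportions; the summed concentrations of a run then reproduce the
#' compartment's total protein concentration exactly.
#'
#' @param intensities Imputed intensity tibble from [impute_missing()].
#' @param totals Tibble (`sample_id`, `compartment`, `total_protein_mg`,
#'   `weight_g`), e.g. from [compartment_totals()].
#' @return Replicate-level concentration tibble (`protein_id`,
#'   `compartment`, `sample_id`, `replicate_id`, `batch_id`,
#'   `concentration`), in mg/g wet compartment.
#' @export
estimate_concentration <- function(intensities, totals) {
  check_stage(intensities, "imputed")
  out <- intensities %>%
    left_join(totals, by = c("sample_id", "compartment"))
  bad <- out %>% filter(is.na(.data$total_protein_mg) | is.na(.data$weight_g))
  if (nrow(bad) > 0) {
    abort(sprintf("no protein total/weight for sample %s (%s)",
                  bad$sample_id[1], bad$compartment[1]))
  }
  out %>%
    group_by(.data$compartment, .data$sample_id, .data$replicate_id) %>%
    mutate(concentration = .data$intensity / sum(.data$intensity) *
             .data$total_protein_mg / .data$weight_g) %>%
    ungroup() %>%
    select("protein_id", "compartment", "sample_id", "replicate_id",
           "batch_id", "concentration")
}

#' Batch-adjusted per-sample protein abundance
#'
#' Collapses technical replicates to one abundance per (protein, sample).
#' With more than one MS batch the per-sample values are the fixed-effect
#' estimates of a linear mixed model `concentration ~ 0 + sample + (1 |
#' batch)` fitted per protein, which absorbs additive batch shifts; with a
#' single batch (or if a fit fails) the replicate mean is used instead.
#'
#' @param conc Replicate-level concentration tibble from
#'   [estimate_concentration()].
#' @return Per-sample concentration tibble (`protein_id`, `compartment`,
#'   `sample_id`, `concentration`).
#' @export
summarize_replicates <- function(conc) {
  fallback <- 0L
  out <- conc %>%
    group_by(.data$protein_id, .data$compartment) %>%
    tidyr::nest(.key = "dat") %>%
    ungroup() %>%
    mutate(res = purrr::map(.data$dat, function(d) {
      means <- d %>%
        group_by(.data$sample_id) %>%
        summarise(concentration = mean(.data$concentration),
                  .groups = "drop")
      if (n_distinct(d$batch_id) < 2 || n_distinct(d$sample_id) < 2) {
        return(means)
      }
      fit <- tryCatch(
        suppressMessages(suppressWarnings(
          lme4::lmer(concentration ~ 0 + sample_id + (1 | batch_id),
                     data = d,
                     control = lme4::lmerControl(calc.derivs = FALSE)))),
        error = function(e) NULL)
      if (is.null(fit)) {
        fallback <<- fallback + 1L
        return(means)
      }
      b <- lme4::fixef(fit)
      tibble(sample_id = sub("^sample_id", "", names(b)),
             concentration = unname(b))
    })) %>%
    select("protein_id", "compartment", "res") %>%
    tidyr::unnest("res")
  if (fallback > 0) {
    inform(sprintf("replicate summarisation fell back to plain means for %d protein(s)",
                   fallback))
  }
  out
}

#' Full quantitation pipeline
#'
#' Identification filter, quantitation filter across biological groups,
#' total-signal normalisation, bounded-uniform imputation, concentration
#' estimation and batch-adjusted replicate summarisation, in that order.
#' Filters are computed on the raw detections.
#'
#' @param intensities Raw long intensity tibble.
#' @param design Egg design tibble (supplies protein totals and weights).
#' @param groups Optional tibble (`sample_id`, `group`); defaults to female
#'   age as the compared biological groups.
#' @param seed Seed for the imputation streams.
#' @return A list of class `egg_quant`: `flags`, `kept`, `replicate_conc`,
#'   `sample_conc` and a `counts` tibble tracking the filters.
#' @export
quantify_proteome <- function(intensities, design, groups = NULL,
                              seed = 1L) {
  groups <- groups %||%
    tibble(sample_id = design$egg_id, group = design$female_age)
  flags <- flag_identified(intensities)
  kept <- filter_quantitated(flags, groups)
  keep_ids <- kept$protein_id[kept$kept]
  filtered <- intensities %>% filter(.data$protein_id %in% keep_ids)
  norm <- normalize_total_signal(filtered)
  imp <- impute_missing(norm, seed = seed)
  conc <- estimate_concentration(imp, compartment_totals(design))
  per_sample <- summarize_replicates(conc)
  counts <- tibble(
    stage = c("input_proteins", "quantitated_proteins", "samples"),
    n = c(n_distinct(intensities$protein_id), length(keep_ids),
          n_distinct(intensities$sample_id)))
  structure(list(flags = flags, kept = kept, replicate_conc = conc,
                 sample_conc = per_sample, counts = counts),
            class = "egg_quant")
}

#' @export
print.egg_quant <- function(x, ...) {
  cat("<egg_quant>\n")
  print(x$counts)
  invisible(x)
}

#' Read a MaxQuant-style wide intensity table
#'
#' Reshapes a proteinGroups-like table whose intensity columns are named
#' `Intensity <sample>_<replicate>` into the long format the pipeline
#' consumes. Zeros are treated as not detected (missing).
#'
#' @param path TSV file path.
#' @param compartment Compartment label to attach.
#' @param batch Optional tibble (`sample_id`, `replicate_id`, `batch_id`);
#'   a single batch is assumed when absent.
#' @param id_col Name of the protein identifier column.
#' @return Long raw intensity tibble.
#' @export
read_maxquant <- function(path, compartment = "albumen", batch = NULL,
                          id_col = "Protein IDs") {
  wide <- utils::read.delim(path, check.names = FALSE, sep = "\t")
  int_cols <- grep("^Intensity .+_", names(wide), value = TRUE)
  if (length(int_cols) == 0) abort("no 'Intensity <sample>_<rep>' columns found")
  long <- as_tibble(wide[, c(id_col, int_cols)]) %>%
    rename(protein_id = !!id_col) %>%
    tidyr::pivot_longer(dplyr::all_of(int_cols), names_to = "run",
                        values_to = "intensity") %>%
    mutate(run = sub("^Intensity ", "", .data$run)) %>%
    tidyr::separate("run", into = c("sample_id", "replicate_id"),
                    sep = "_(?=[^_]+$)") %>%
    mutate(replicate_id = as.integer(.data$replicate_id),
           compartment = compartment,
           intensity = if_else(.data$intensity > 0,
                               as.numeric(.data$intensity), NA_real_))
  if (is.null(batch)) {
    long$batch_id <- "MS01"
  } else {
    long <- left_join(long, batch, by = c("sample_id", "replicate_id"))
  }
  out <- long %>%
    select("protein_id", "compartment", "sample_id", "replicate_id",
           "batch_id", "intensity")
  attr(out, "stage") <- "raw"
  out
}

check_stage <- function(x, expected) {
  stage <- attr(x, "stage") %||% "raw"
  if (!identical(stage, expected)) {
    abort(sprintf("expected a %s-stage intensity table, got %s",
                  expected, stage))
  }
  invisible(x)
}
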