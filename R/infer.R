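#' Two-SD standardisation
#'
#' Centres a numeric vector and divides by twice its standard deviation
#' (denominator n-1), putting continuous predictors on the same scale as
#' untransformed 0/1 binary predictors so their effect sizes are directly
#' comparable.
#'
#' @param x Numeric vector with at least two distinct non-missing values.
#' @return The standardised vector (SD = 0.5).
#' @examples
#' standardize_2sd(c(0, 2)) # -0.3536  0.3536
#' @export
standardize_2sd <- function(x) {
  s <- sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) abort("cannot standardise: zero variance")
  (x - mean(x, na.rm = TRUE)) / (2 * s)
}

#' Average-rank transform
#'
#' Ranks a vector with average ranks for ties; used on protein
#' concentration estimates so that models are robust to the extreme values
#' label-free abundances produce.
#' @param x Numeric vector.
#' @return Numeric ranks (ties share their average rank).
#' @export
rank_transform <- function(x) {
  rank(x, ties.method = "average", na.last = "keep")
}

binary_codes <- list(
  female_age = c(yearling = 0, adult = 1),
  embryo_sex = c(female = 0, male = 1),
  paternity = c("within-pair" = 0, "extra-pair" = 1)
)

prepare_model_frame <- function(data, response, predictors,
                                transform = "none",
                                female_col = "female_id",
                                batch_col = NULL,
                                standardize_response = TRUE) {
  stopifnot(response %in% names(data))
  keep <- c(response, predictors, female_col, batch_col, "laying_order")
  df <- data %>%
    select(dplyr::all_of(unique(keep[keep %in% names(data)]))) %>%
    filter(stats::complete.cases(.))
  if ("paternity" %in% predictors) {
    df <- df %>% filter(.data$paternity != "unknown")
  }
  y <- df[[response]]
  if (transform == "rank") y <- rank_transform(y)
  if (transform == "log") {
    if (any(y <= 0)) abort("log transform requires positive response values")
    y <- log(y)
  }
  df$.y <- if (standardize_response) standardize_2sd(y) else y
  for (p in predictors) {
    if (p %in% names(binary_codes)) {
      codes <- binary_codes[[p]]
      bad <- setdiff(unique(df[[p]]), names(codes))
      if (length(bad)) abort(sprintf("unknown level in %s: %s", p, bad[1]))
      df[[p]] <- unname(codes[df[[p]]])
    } else {
      df[[p]] <- standardize_2sd(df[[p]])
    }
  }
  if (!("laying_order" %in% predictors) &&
      "laying_order" %in% names(df) &&
      n_distinct(df$laying_order) > 1) {
    df$laying_order <- standardize_2sd(df$laying_order)
  }
  df
}

#' Standardised linear mixed model for one egg-level response
#'
#' Fits, by REML, a Gaussian linear mixed model with female identity as
#' random intercept and laying order as random slope, plus (optionally) an
#' assay-batch random intercept. The response is transformed (`none`,
#' `rank` for protein concentrations, `log` for carotenoids) and then
#' 2-SD-standardised; continuous predictors are 2-SD-standardised and
#' binary predictors are coded 0/1 (yearling/female/within-pair = 0), so
#' all coefficients are standardised effect sizes. Inference is Wald:
#' z = beta/SE with normal 95% CIs. Models including paternity are
#' restricted to first-laid eggs. A singular random-slope fit is refitted
#' without the slope and flagged.
#'
#' @param data Egg-level tibble; must contain `response`, the predictors,
#'   `female_id` and `laying_order`.
#' @param response Response column name.
#' @param predictors Character vector of fixed-effect terms among
#'   `laying_order`, `female_age`, `lay_date`, `clutch_size`, `egg_weight`,
#'   `embryo_sex`, `paternity`.
#' @param interactions Optional character vector like
#'   `"female_age:laying_order"`.
#' @param transform One of `"none"`, `"rank"`, `"log"`.
#' @param batch_col Optional assay-batch column added as a random
#'   intercept (MS or HPLC batch).
#' @param random_slope Include the laying-order random slope (default TRUE).
#' @param model_id Label stored with the estimates.
#' @return An object of class `egg_lmm`; see [tidy.egg_lmm()] and
#'   [glance.egg_lmm()].
#' @export
fit_egg_lmm <- function(data, response,
                        predictors = c("laying_order", "female_age",
                                       "lay_date", "clutch_size",
                                       "embryo_sex"),
                        interactions = NULL,
                        transform = c("none", "rank", "log"),
                        batch_col = NULL,
                        random_slope = TRUE,
                        model_id = response) {
  transform <- match.arg(transform)
  if ("paternity" %in% predictors) {
    data <- data %>% filter(.data$laying_order == 1)
  }
  df <- prepare_model_frame(data, response, predictors,
                            transform = transform, batch_col = batch_col)
  if (n_distinct(df$female_id) < 2) abort("need >= 2 females")
  fixed <- paste(c(predictors, interactions), collapse = " + ")
  # with one egg per female (first-egg subsets) the female intercept is
  # unidentifiable and is dropped
  female_re <- max(table(df$female_id)) >= 2
  slope_ok <- female_re && random_slope && n_distinct(df$laying_order) > 1
  re <- character(0)
  if (female_re) {
    re <- if (slope_ok) "(1 + laying_order | female_id)" else
      "(1 | female_id)"
  }
  if (!is.null(batch_col)) re <- c(re, sprintf("(1 | %s)", batch_col))

  fit_formula <- function(re_terms) {
    rhs <- paste(c(fixed, re_terms), collapse = " + ")
    as.formula(paste(".y ~", rhs))
  }
  do_fit <- function(re_terms) {
    if (length(re_terms) == 0) {
      stats::lm(fit_formula(NULL), data = df)
    } else {
      suppressMessages(suppressWarnings(
        lme4::lmer(fit_formula(re_terms), data = df, REML = TRUE)))
    }
  }
  fit <- do_fit(re)
  dropped_slope <- FALSE
  if (slope_ok && lme4::isSingular(fit, tol = 1e-5)) {
    re <- c("(1 | female_id)",
            if (!is.null(batch_col)) sprintf("(1 | %s)", batch_col))
    fit <- do_fit(re)
    dropped_slope <- TRUE
  }

  b <- if (inherits(fit, "merMod")) lme4::fixef(fit) else coef(fit)
  V <- as.matrix(vcov(fit))
  se <- sqrt(diag(V))
  terms <- setdiff(names(b), "(Intercept)")
  # report interactions under the labels they were requested with
  if (!is.null(interactions)) {
    canon <- function(t) {
      vapply(strsplit(t, ":", fixed = TRUE),
             function(p) paste(sort(p), collapse = ":"), character(1))
    }
    for (ia in interactions) {
      names(b)[canon(names(b)) == canon(ia)] <- ia
    }
    terms <- setdiff(names(b), "(Intercept)")
  }
  z <- b / se
  est <- tibble(
    model = model_id,
    term = names(b),
    estimate = unname(b),
    std_error = unname(se),
    conf_low = unname(b - 1.96 * se),
    conf_high = unname(b + 1.96 * se),
    statistic = unname(z),
    p_raw = unname(2 * pnorm(-abs(z)))
  ) %>% filter(.data$term %in% terms)

  structure(list(fit = fit, estimates = est, model_id = model_id,
                 response = response, transform = transform,
                 predictors = predictors, interactions = interactions,
                 dropped_slope = dropped_slope, n = nrow(df),
                 n_females = n_distinct(df$female_id)),
            class = "egg_lmm")
}

#' @export
print.egg_lmm <- function(x, ...) {
  cat(sprintf("<egg_lmm> %s (%s-transformed, n = %d eggs, %d females%s)\n",
              x$model_id, x$transform, x$n, x$n_females,
              if (x$dropped_slope) ", random slope dropped" else ""))
  print(x$estimates)
  invisible(x)
}

#' @describeIn fit_egg_lmm Tidy the standardised effect estimates.
#' @param x An `egg_lmm` object.
#' @param ... Unused.
#' @method tidy egg_lmm
#' @export
tidy.egg_lmm <- function(x, ...) x$estimates

#' @describeIn fit_egg_lmm One-row model summary (variance components,
#'   sample sizes, whether the random slope was dropped as singular).
#' @method glance egg_lmm
#' @export
glance.egg_lmm <- function(x, ...) {
  if (!inherits(x$fit, "merMod")) {
    return(tibble(model = x$model_id, n = x$n, n_females = x$n_females,
                  sd_female = NA_real_, sd_slope = NA_real_,
                  sd_residual = stats::sigma(x$fit),
                  dropped_slope = x$dropped_slope))
  }
  vc <- as.data.frame(lme4::VarCorr(x$fit))
  fe_sd <- function(grp, var) {
    hit <- vc$grp == grp & !is.na(vc$var1) & vc$var1 == var & is.na(vc$var2)
    if (any(hit)) vc$sdcor[hit][1] else NA_real_
  }
  tibble(
    model = x$model_id,
    n = x$n, n_females = x$n_females,
    sd_female = fe_sd("female_id", "(Intercept)"),
    sd_slope = fe_sd("female_id", "laying_order"),
    sd_residual = vc$sdcor[vc$grp == "Residual"][1],
    dropped_slope = x$dropped_slope
  )
}

#' Between- versus within-female variance partition
#'
#' Intercept-only linear mixed model with female identity as random
#' intercept; the between-female percentage is
#' 100 * var(female) / (var(female) + var(residual)) — the intraclass
#' correlation on the percentage scale.
#'
#' @param data Egg-level tibble.
#' @param response Response column name.
#' @param female_col Grouping column (default `female_id`).
#' @return Tibble (`response`, `between_pct`, `within_pct`).
#' @export
variance_partition <- function(data, response, female_col = "female_id") {
  df <- tibble(.y = data[[response]], fem = data[[female_col]]) %>%
    filter(!is.na(.data$.y))
  if (n_distinct(df$fem) < 2) abort("need >= 2 females")
  if (!any(table(df$fem) >= 2)) abort("need >= 2 eggs in at least one female")
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(.y ~ 1 + (1 | fem), data = df, REML = TRUE))),
    error = function(e) NULL)
  if (is.null(fit)) {
    warn("degenerate intercept-only fit; reporting 0% between females")
    return(tibble(response = response, between_pct = 0, within_pct = 100))
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  v_f <- vc$vcov[vc$grp == "fem"][1]
  v_r <- vc$vcov[vc$grp == "Residual"][1]
  tibble(response = response,
         between_pct = 100 * v_f / (v_f + v_r),
         within_pct = 100 * v_r / (v_f + v_r))
}

#' Single-step and FDR p-value adjustment
#'
#' Within each model, p-values are corrected single-step style: the
#' adjusted p of a contrast is the probability that the largest absolute
#' z-statistic of the model's joint (multivariate-normal) contrasts exceeds
#' the observed one, evaluated by Monte Carlo under the fitted correlation
#' of the estimates (a fixed internal seed makes it reproducible). Across
#' models, Benjamini-Hochberg FDR is applied to the single-step values per
#' term family, but only when the family counts at least `min_models`
#' models. Adjusted values never fall below the raw ones.
#'
#' @param fits List of `egg_lmm` objects (or a single one).
#' @param family Optional character vector (recycled) labelling the
#'   analysis family of each fit; defaults to one family.
#' @param min_models Minimum family size for FDR (default 5).
#' @param nsim Monte-Carlo draws for the single-step correction.
#' @param seed Seed for the Monte-Carlo draws.
#' @return Tibble of estimates with `p_single_step` and `p_fdr` columns.
#' @export
adjust_pvalues <- function(fits, family = "all", min_models = 5L,
                           nsim = 1e5, seed = 20141009L) {
  if (inherits(fits, "egg_lmm")) fits <- list(fits)
  family <- rep_len(family, length(fits))
  est <- purrr::map2_dfr(fits, family, function(f, fam) {
    tidy(f) %>%
      mutate(family = fam,
             p_single_step = single_step_p(f, nsim = nsim, seed = seed))
  })
  est %>%
    group_by(.data$family, .data$term) %>%
    mutate(p_fdr = if (dplyr::n() >= min_models) {
      pmax(p.adjust(.data$p_single_step, method = "BH"),
           .data$p_single_step)
    } else .data$p_single_step) %>%
    ungroup()
}

single_step_p <- function(fit, nsim = 1e5, seed = 20141009L) {
  est <- fit$estimates
  if (nrow(est) <= 1) return(est$p_raw)
  V <- as.matrix(vcov(fit$fit))
  V <- V[est$term, est$term, drop = FALSE]
  pmax(max_z_adjust(est$statistic, stats::cov2cor(V), nsim = nsim,
                    seed = seed),
       est$p_raw)
}

#' Max-|z| multiplicity adjustment under a joint normal
#'
#' Monte-Carlo single-step correction: the adjusted p of each statistic is
#' the probability that the maximum absolute component of a multivariate
#' normal with correlation `R` reaches the observed |z|.
#'
#' @param z Observed z-statistics.
#' @param R Correlation matrix of the statistics.
#' @param nsim Number of Monte-Carlo draws.
#' @param seed Seed for the draws.
#' @return Adjusted p-values, one per statistic.
#' @export
max_z_adjust <- function(z, R, nsim = 1e5, seed = 20141009L) {
  k <- length(z)
  stopifnot(nrow(R) == k, ncol(R) == k)
  draws <- abs(withr::with_seed(
    seed, MASS::mvrnorm(nsim, mu = rep(0, k), Sigma = R)))
  maxabs <- do.call(pmax, as.data.frame(draws))
  vapply(abs(z), function(zi) mean(maxabs >= zi), numeric(1))
}

#' A-priori interaction tests
#'
#' Adds, one at a time, the three interactions chosen a priori — female
#' age x laying order, female age x clutch size and embryo sex x laying
#' order — to the main-effects model of a response and returns their
#' standardised estimates. They are meant to be FDR-adjusted together with
#' the main-effect model battery.
#'
#' @inheritParams fit_egg_lmm
#' @return A list of three `egg_lmm` fits, named by interaction.
#' @export
test_interactions <- function(data, response,
                              predictors = c("laying_order", "female_age",
                                             "lay_date", "clutch_size",
                                             "embryo_sex"),
                              transform = "none", batch_col = NULL) {
  pairs <- c("female_age:laying_order",
             "female_age:clutch_size",
             "embryo_sex:laying_order")
  fits <- purrr::map(pairs, function(ia) {
    fit_egg_lmm(data, response, predictors = predictors,
                interactions = ia, transform = transform,
                batch_col = batch_col,
                model_id = paste(response, ia, sep = ":"))
  })
  names(fits) <- pairs
  fits
}

#' Fit the standardised model battery over many responses
#'
#' One mixed model per response column, all with the same predictors and
#' random structure, followed by single-step and (family-wise) FDR
#' adjustment. This is the engine behind per-protein, per-carotenoid and
#' per-cluster-sum inference.
#'
#' @param data Egg-level tibble containing all responses and predictors.
#' @param responses Character vector of response column names.
#' @param transform Response transform applied to every model.
#' @param family Family label used for the FDR step.
#' @inheritParams fit_egg_lmm
#' @inheritParams adjust_pvalues
#' @return Tibble of adjusted estimates, one row per (model, term).
#' @export
fit_model_battery <- function(data, responses,
                              predictors = c("laying_order", "female_age",
                                             "lay_date", "clutch_size",
                                             "embryo_sex"),
                              transform = "none", batch_col = NULL,
                              family = "battery", nsim = 1e5,
                              seed = 20141009L) {
  fits <- purrr::map(responses, function(r) {
    fit_egg_lmm(data, r, predictors = predictors, transform = transform,
                batch_col = batch_col, model_id = r)
  })
  adjust_pvalues(fits, family = family, nsim = nsim, seed = seed)
}
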