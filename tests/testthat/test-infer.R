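test_that("2-SD standardisation matches the closed form and is affine-invariant", {
  expect_equal(standardize_2sd(c(0, 2)),
               c(-0.5, 0.5) / sqrt(2), tolerance = 1e-9)
  x <- rnorm(50)
  expect_equal(sd(standardize_2sd(x)), 0.5, tolerance = 1e-12)
  expect_equal(standardize_2sd(3 + 7 * x), standardize_2sd(x),
               tolerance = 1e-9)
  expect_error(standardize_2sd(rep(1, 5)), "zero variance")
})

test_that("rank transform averages ties and is idempotent up to scale", {
  expect_equal(rank_transform(c(3.2, 1.1, 9.9)), c(2, 1, 3))
  expect_equal(rank_transform(c(5, 5, 1)), c(2.5, 2.5, 1))
  for (i in 1:10) {
    x <- rnorm(30)
    r <- rank_transform(x)
    expect_equal(rank_transform(r), r)
    expect_true(all(diff(r[order(x)]) >= 0))
  }
})

test_that("variance partition recovers constructed intraclass correlations", {
  # large balanced design, sigma2_female = 4, sigma2_resid = 1 -> 80%
  set.seed(5)
  nf <- 150; k <- 8
  d <- tibble::tibble(
    female_id = rep(sprintf("F%03d", 1:nf), each = k),
    y = rep(rnorm(nf, 0, 2), each = k) + rnorm(nf * k, 0, 1))
  vp <- variance_partition(d, "y")
  expect_lt(abs(vp$between_pct - 80), 4)
  expect_equal(vp$between_pct + vp$within_pct, 100, tolerance = 1e-6)
  # females differ, all their eggs identical -> 100%
  d2 <- tibble::tibble(female_id = rep(c("A", "B", "C"), each = 3),
                       y = rep(c(1, 5, 9), each = 3))
  expect_gt(variance_partition(d2, "y")$between_pct, 99.9)
  # indistinguishable females -> ~0%
  d3 <- tibble::tibble(female_id = rep(sprintf("F%02d", 1:40), each = 10),
                       y = rnorm(400))
  expect_lt(variance_partition(d3, "y")$between_pct, 10)
})

test_that("standardised effects are invariant to affine rescaling of the data", {
  d <- simulate_design(study_config(seed = 31))
  f1 <- fit_egg_lmm(d, "egg_weight")
  d2 <- d %>% dplyr::mutate(egg_weight = 1000 * egg_weight - 3,
                            lay_date = lay_date * 2 + 10)
  f2 <- fit_egg_lmm(d2, "egg_weight")
  expect_equal(tidy(f1)$estimate, tidy(f2)$estimate, tolerance = 1e-6)
  expect_equal(tidy(f1)$statistic, tidy(f2)$statistic, tolerance = 1e-5)
})

test_that("a zero-variance random slope is dropped without moving the estimates", {
  set.seed(8)
  d <- simulate_design(study_config(seed = 8, order_slope_yearling = 0,
                                    order_slope_adult = 0))
  # response with no female-by-order slope at all
  d$y <- 2 + 0.3 * d$egg_weight + rnorm(nrow(d), 0, 0.2)
  with_slope <- fit_egg_lmm(d, "y")
  no_slope <- fit_egg_lmm(d, "y", random_slope = FALSE)
  if (with_slope$dropped_slope) {
    expect_equal(tidy(with_slope)$estimate, tidy(no_slope)$estimate,
                 tolerance = 1e-6)
  } else {
    expect_equal(tidy(with_slope)$estimate, tidy(no_slope)$estimate,
                 tolerance = 0.02)
  }
})

test_that("paternity models are restricted to first-laid assigned eggs", {
  d <- simulate_design(study_config(seed = 13))
  fit <- fit_egg_lmm(d, "egg_weight",
                     predictors = c("female_age", "paternity"))
  n_first_assigned <- sum(d$laying_order == 1 & d$paternity != "unknown")
  expect_equal(fit$n, n_first_assigned)
  expect_true("paternity" %in% tidy(fit)$term)
})

test_that("single-step correction matches closed forms and multcomp", {
  # a single contrast is left untouched
  d <- simulate_design(study_config(seed = 17))
  f1 <- fit_egg_lmm(d, "egg_weight", predictors = "laying_order")
  adj1 <- adjust_pvalues(f1)
  expect_equal(adj1$p_single_step, adj1$p_raw)
  # two independent contrasts: p_adj = 1 - (1 - p)^2
  p_adj <- max_z_adjust(rep(qnorm(1 - 0.025), 2), diag(2), nsim = 2e5,
                        seed = 1)
  expect_lt(abs(p_adj[1] - (1 - 0.95^2)), 0.004)
  # agreement with the reference single-step implementation
  skip_if_not_installed("multcomp")
  f <- fit_egg_lmm(d, "egg_weight")
  adj <- adjust_pvalues(f, nsim = 2e5)
  K <- diag(length(lme4::fixef(f$fit)))[-1, , drop = FALSE]
  rownames(K) <- tidy(f)$term
  ref <- summary(multcomp::glht(f$fit, linfct = K))
  expect_equal(adj$p_single_step,
               as.numeric(ref$test$pvalues), tolerance = 0.01)
})

test_that("FDR is applied per family only when five or more models ran", {
  d <- simulate_design(study_config(seed = 23))
  responses <- c("egg_weight", "albumen_weight", "yolk_weight",
                 "albumen_protein_mgg", "yolk_protein_mgg")
  batt <- fit_model_battery(d, responses, nsim = 2e4)
  expect_true(all(batt$p_fdr >= batt$p_single_step - 1e-12))
  expect_true(all(batt$p_single_step >= batt$p_raw - 1e-12))
  # FDR-significant set is a subset of the raw-significant set
  expect_true(all(batt$p_raw[batt$p_fdr < 0.05] < 0.05))
  # small family: no FDR applied
  two <- adjust_pvalues(list(
    fit_egg_lmm(d, "egg_weight"),
    fit_egg_lmm(d, "yolk_weight")), nsim = 1e4)
  expect_equal(two$p_fdr, two$p_single_step)
})

test_that("exactly the three a-priori interactions are tested", {
  d <- simulate_design(study_config(seed = 19))
  fits <- test_interactions(d, "egg_weight")
  expect_length(fits, 3)
  terms <- unlist(lapply(fits, function(f) {
    grep(":", tidy(f)$term, value = TRUE)
  }))
  expect_setequal(unname(terms),
                  c("female_age:laying_order", "female_age:clutch_size",
                    "embryo_sex:laying_order"))
})

test_that("an age-by-order interaction in the generator is detected", {
  # yearlings and adults get opposite within-clutch trends by default;
  # amplify them and the interaction term must show up
  cfg <- study_config(seed = 29, order_slope_yearling = 0.02,
                      order_slope_adult = -0.02)
  d <- simulate_design(cfg)
  fits <- test_interactions(d, "egg_weight")
  p <- tidy(fits[["female_age:laying_order"]]) %>%
    dplyr::filter(term == "female_age:laying_order") %>%
    dplyr::pull(p_raw)
  expect_lt(p, 0.05)
})
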