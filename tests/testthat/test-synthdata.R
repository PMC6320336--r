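test_that("default design reproduces the field sampling scheme", {
  d <- simulate_design(study_config(seed = 11))
  expect_equal(nrow(d), 114)
  expect_equal(dplyr::n_distinct(d$female_id), 39)
  # partially sampled clutches contribute eggs 1 and 9 only
  by_female <- split(d$laying_order, d$female_id)
  n_two <- sum(vapply(by_female, function(x) identical(sort(x), c(1L, 9L)),
                      logical(1)))
  expect_equal(n_two, 29)
  # fully sampled clutches contribute every odd position up to clutch size
  full <- by_female[vapply(by_female, length, integer(1)) > 2]
  expect_length(full, 10)
  for (f in names(full)) {
    size <- d$clutch_size[d$female_id == f][1]
    expect_equal(sort(full[[f]]), seq(1L, size, by = 2L))
  }
  # record-level invariants
  expect_true(all(d$albumen_weight + d$yolk_weight < d$egg_weight))
  expect_true(all(d$egg_weight > 0 & d$yolk_weight > 0))
  expect_true(all(d$laying_order <= d$clutch_size))
  expect_true(all(d$laying_order[d$paternity == "extra-pair"] == 1))
})

test_that("single partially sampled clutch yields exactly eggs 1 and 9", {
  cfg <- study_config(n_clutches = 1, n_full_clutches = 0,
                      full_clutch_sizes = integer(0), n_unassigned = 0,
                      seed = 3)
  d <- simulate_design(cfg)
  expect_equal(nrow(d), 2)
  expect_setequal(d$laying_order, c(1L, 9L))
})

test_that("extra-pair fraction among assigned eggs sits in the binomial band around 12%", {
  # 95% band for n ~ 108 assigned eggs at p = 0.12
  fracs <- vapply(1:8, function(s) {
    d <- simulate_design(study_config(seed = s))
    a <- d[d$paternity != "unknown", ]
    mean(a$paternity == "extra-pair")
  }, numeric(1))
  n <- 108
  band <- 0.12 + c(-1, 1) * 1.96 * sqrt(0.12 * 0.88 / n)
  expect_true(mean(fracs >= band[1] & fracs <= band[2]) >= 6 / 8)
  expect_true(abs(mean(fracs) - 0.12) < 0.05)
})

test_that("fixed seed gives bit-identical datasets and bad configs error", {
  s1 <- simulate_study(small_config(seed = 5))
  s2 <- simulate_study(small_config(seed = 5))
  expect_identical(s1$design, s2$design)
  expect_identical(s1$intensities, s2$intensities)
  expect_identical(s1$carotenoids, s2$carotenoids)
  expect_error(study_config(clutch_size_range = c(15, 7)), "min <= max")
  expect_error(study_config(ep_rate_first_eggs = 1.2), "proportion")
  expect_error(study_config(n_funcat_terms = 0), "count")
})

test_that("degenerate ground truth collapses every replicate to the baseline", {
  cfg <- small_config(seed = 2)
  d <- simulate_design(cfg)
  prot <- simulate_proteome(d, null_ground_truth(cfg), cfg)
  tab <- prot$intensities
  expect_false(anyNA(tab$intensity))
  base <- ground_truth(cfg, frac_affected = 0)$coefficients
  ref <- exp(base$baseline[match(tab$protein_id, base$protein_id)])
  expect_equal(tab$intensity, ref, tolerance = 1e-12)
})

test_that("missingness is intensity-dependent (MNAR) at roughly the configured rate", {
  cfg <- study_config(seed = 7, n_albumen_proteins = 120,
                      n_yolk_proteins = 0)
  d <- simulate_design(cfg)
  truth <- ground_truth(cfg)
  prot <- simulate_proteome(d, truth, cfg)
  byp <- prot$intensities %>%
    dplyr::group_by(protein_id) %>%
    dplyr::summarise(miss = mean(is.na(intensity)))
  base <- truth$coefficients$baseline[match(byp$protein_id,
                                            truth$coefficients$protein_id)]
  expect_lt(cor(base, byp$miss, method = "spearman"), -0.5)
  expect_true(abs(mean(is.na(prot$intensities$intensity)) - 0.15) < 0.03)
})

test_that("functional annotations use 21 terms with 1-16 terms per protein", {
  st <- simulate_study(study_config(seed = 4))
  per_prot <- st$annotations %>% dplyr::count(protein_id)
  expect_true(all(per_prot$n >= 1 & per_prot$n <= 16))
  expect_lte(dplyr::n_distinct(st$annotations$term_id), 21)
  expect_true(all(grepl("^FC\\d+$", st$annotations$term_id)))
  expect_equal(sort(unique(per_prot$protein_id)),
               sort(unique(st$intensities$protein_id)))
})

test_that("carotenoid generator hits the panel means and detection rates", {
  st <- simulate_study(study_config(seed = 21))
  lut <- st$carotenoids %>% dplyr::filter(species == "lutein")
  se <- sd(lut$concentration_ugg) / sqrt(nrow(lut))
  expect_lt(abs(mean(lut$concentration_ugg) - 22.1), 3 * se + 1e-9)
  # detection fraction pooled over five datasets (n = 570 eggs)
  det <- unlist(lapply(21:25, function(s) {
    bz <- simulate_study(study_config(seed = s))$carotenoids %>%
      dplyr::filter(species == "beta-zeacarotene")
    !is.na(bz$concentration_ugg)
  }))
  band <- 0.67 + c(-1, 1) * 1.96 * sqrt(0.67 * 0.33 / length(det))
  expect_true(mean(det) >= band[1] && mean(det) <= band[2])
})

test_that("carotenoid species are mutually positively correlated (shared source)", {
  st <- simulate_study(study_config(seed = 8))
  wide <- st$carotenoids %>%
    dplyr::filter(species != "beta-zeacarotene") %>%
    tidyr::pivot_wider(id_cols = egg_id, names_from = species,
                       values_from = concentration_ugg)
  cc <- cor(log(as.matrix(wide[, -1])))
  expect_true(all(cc[upper.tri(cc)] > 0))
})

test_that("a null laying-order effect produces no spurious carotenoid trend", {
  hits <- vapply(1:40, function(s) {
    cfg <- study_config(seed = s)
    d <- simulate_design(cfg)
    chem <- simulate_yolk_chemistry(d, cfg, order_effect_carotenoid = 0)
    tot <- total_carotenoids(chem$carotenoids) %>%
      dplyr::left_join(d, by = "egg_id")
    fit <- summary(lm(log(total_carotenoid_ugg) ~ laying_order, data = tot))
    fit$coefficients["laying_order", "Pr(>|t|)"] < 0.05
  }, logical(1))
  expect_lte(mean(hits), 0.10)
})

test_that("study TSVs round-trip through write_study", {
  st <- simulate_study(small_config(seed = 6))
  dir <- withr::local_tempdir()
  write_study(st, dir)
  expect_true(all(file.exists(file.path(
    dir, c("metadata.tsv", "intensities.tsv", "annotations.tsv",
           "carotenoids.tsv", "lipids.tsv", "ground_truth.tsv")))))
  meta <- utils::read.delim(file.path(dir, "metadata.tsv"))
  expect_equal(nrow(meta), nrow(st$design))
})
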