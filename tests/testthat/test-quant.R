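test_that("identification needs positive intensities in two replicates", {
  tab <- make_intensity_table(list(
    P1 = list(S1 = c(5.0, NA, 3.0)),
    P2 = list(S1 = c(5.0, NA, NA)),
    P3 = list(S1 = c(0, 4, 2))
  ))
  flags <- flag_identified(tab)
  expect_true(flags$identified[flags$protein_id == "P1"])
  expect_false(flags$identified[flags$protein_id == "P2"])
  expect_true(flags$identified[flags$protein_id == "P3"])
  # a single-replicate sample can never be identified, and is flagged
  tab1 <- make_intensity_table(list(P1 = list(S1 = 9)))
  expect_warning(f1 <- flag_identified(tab1), "single replicate")
  expect_false(f1$identified)
})

test_that("identified fraction matches the binomial closed form", {
  # detection prob p = 0.5 per replicate, 3 replicates:
  # P(identified) = P(Bin(3, 0.5) >= 2) = 0.5
  set.seed(42)
  n <- 4000
  vals <- matrix(ifelse(runif(3 * n) < 0.5, 10, NA), ncol = 3)
  tab <- tibble::tibble(
    protein_id = rep(sprintf("P%04d", 1:n), each = 3),
    compartment = "albumen",
    sample_id = "S1",
    replicate_id = rep(1:3, n),
    batch_id = "MS01",
    intensity = as.vector(t(vals)))
  attr(tab, "stage") <- "raw"
  frac <- mean(flag_identified(tab)$identified)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n))
})

test_that("quantitation keeps proteins identified in half of one group", {
  mk_flags <- function(identified, samples) {
    tibble::tibble(protein_id = "P1", compartment = "albumen",
                   sample_id = samples, n_positive = 2,
                   identified = identified)
  }
  groups <- tibble::tibble(sample_id = sprintf("S%02d", 1:20),
                           group = rep(c("A", "B"), each = 10))
  f1 <- mk_flags(c(rep(TRUE, 6), rep(FALSE, 14)), groups$sample_id)
  expect_true(filter_quantitated(f1, groups)$kept)
  f2 <- mk_flags(rep(c(rep(TRUE, 4), rep(FALSE, 6)), 2), groups$sample_id)
  # 4/10 in each group: below half in both
  expect_false(filter_quantitated(f2, groups)$kept)
  expect_error(filter_quantitated(f1, groups[0, ]), "without a group")
})

test_that("quantitation rule matches exhaustive enumeration over patterns", {
  # all 2^6 identification patterns, two groups of 3
  groups <- tibble::tibble(sample_id = sprintf("S%d", 1:6),
                           group = rep(c("A", "B"), each = 3))
  for (mask in 0:63) {
    ident <- as.logical(bitwAnd(mask, 2^(0:5)))
    flags <- tibble::tibble(protein_id = "P", compartment = "albumen",
                            sample_id = groups$sample_id,
                            n_positive = 2, identified = ident)
    expected <- sum(ident[1:3]) >= 2 || sum(ident[4:6]) >= 2
    expect_identical(filter_quantitated(flags, groups)$kept, expected)
  }
})

test_that("total-signal normalisation makes every run sum to one", {
  tab <- make_intensity_table(list(
    P1 = list(S1 = c(2, 7)), P2 = list(S1 = c(3, NA)),
    P3 = list(S1 = c(5, NA))))
  norm <- normalize_total_signal(tab)
  r1 <- norm$intensity[norm$replicate_id == 1]
  expect_equal(sort(r1), c(0.2, 0.3, 0.5))
  expect_equal(norm$intensity[norm$replicate_id == 2 &
                                norm$protein_id == "P1"], 1.0)
  # property: random tables always renormalise to unit run sums
  set.seed(1)
  for (i in 1:20) {
    st <- simulate_study(small_config(seed = i))
    n <- normalize_total_signal(st$intensities)
    sums <- n %>%
      dplyr::group_by(compartment, sample_id, replicate_id) %>%
      dplyr::summarise(s = sum(intensity, na.rm = TRUE), .groups = "drop")
    expect_true(all(abs(sums$s - 1) < 1e-9))
  }
  bad <- make_intensity_table(list(P1 = list(S1 = c(1, NA)),
                                   P2 = list(S1 = c(2, NA))))
  expect_error(normalize_total_signal(bad), "zero total")
})

test_that("imputed values respect the [min, 1% quantile] bounds", {
  set.seed(3)
  obs <- runif(200, 0.001, 0.05)
  tab <- tibble::tibble(
    protein_id = sprintf("P%03d", 1:260), compartment = "albumen",
    sample_id = "S1", replicate_id = 1L, batch_id = "MS01",
    intensity = c(obs / sum(obs), rep(NA, 60)))
  attr(tab, "stage") <- "normalized"
  imp <- impute_missing(tab, seed = 9)
  filled <- imp$intensity[is.na(tab$intensity[match(imp$protein_id,
                                                    tab$protein_id)])]
  lo <- min(obs / sum(obs))
  hi <- quantile(obs / sum(obs), 0.01, type = 7)
  expect_true(all(filled >= lo & filled <= hi))
  # deterministic for a fixed seed, different for another
  imp2 <- impute_missing(tab, seed = 9)
  expect_identical(imp$intensity, imp2$intensity)
  imp3 <- impute_missing(tab, seed = 10)
  expect_false(identical(imp$intensity, imp3$intensity))
})

test_that("degenerate imputation interval collapses to a constant", {
  tab <- tibble::tibble(
    protein_id = c("P1", "P2", "P3"), compartment = "albumen",
    sample_id = "S1", replicate_id = 1L, batch_id = "MS01",
    intensity = c(0.5, 0.5, NA))
  attr(tab, "stage") <- "normalized"
  imp <- impute_missing(tab, seed = 1)
  expect_equal(imp$intensity[imp$protein_id == "P3"], 0.5)
  none <- tibble::tibble(
    protein_id = "P1", compartment = "albumen", sample_id = "S1",
    replicate_id = 1L, batch_id = "MS01", intensity = NA_real_)
  attr(none, "stage") <- "normalized"
  expect_error(impute_missing(none), "no observed values")
})

test_that("concentration estimation is the normalised share of total protein", {
  # share 0.2 of 43.4 mg total in a 0.83 g albumen: 10.458 mg/g
  tab <- tibble::tibble(
    protein_id = c("P1", "P2", "P3"), compartment = "albumen",
    sample_id = "S1", replicate_id = 1L, batch_id = "MS01",
    intensity = c(0.2, 0.3, 0.5))
  attr(tab, "stage") <- "imputed"
  totals <- tibble::tibble(sample_id = "S1", compartment = "albumen",
                           total_protein_mg = 43.4, weight_g = 0.83)
  conc <- estimate_concentration(tab, totals)
  expect_equal(conc$concentration[conc$protein_id == "P1"],
               0.2 * 43.4 / 0.83, tolerance = 1e-12)
  expect_equal(sum(conc$concentration), 43.4 / 0.83, tolerance = 1e-9)
  # single-protein run: concentration is exactly total/weight
  one <- tab[1, ] %>% dplyr::mutate(intensity = 1)
  attr(one, "stage") <- "imputed"
  expect_equal(estimate_concentration(one, totals)$concentration,
               43.4 / 0.83)
  expect_error(estimate_concentration(tab, totals[0, ]), "no protein total")
})

test_that("per-sample concentrations conserve the compartment total", {
  st <- simulate_study(small_config(seed = 12))
  q <- suppressWarnings(suppressMessages(
    quantify_proteome(st$intensities, st$design)))
  chk <- q$replicate_conc %>%
    dplyr::group_by(compartment, sample_id, replicate_id) %>%
    dplyr::summarise(s = sum(concentration), .groups = "drop") %>%
    dplyr::left_join(compartment_totals(st$design),
                     by = c("sample_id", "compartment"))
  expect_true(all(abs(chk$s / (chk$total_protein_mg / chk$weight_g) - 1)
                  < 1e-6))
  # pipeline composition preserves keys: no invented proteins or samples
  expect_true(all(q$sample_conc$protein_id %in% st$intensities$protein_id))
  expect_equal(dplyr::n_distinct(q$sample_conc$sample_id),
               dplyr::n_distinct(st$intensities$sample_id))
})

test_that("replicate summarisation collapses to means with a single batch", {
  conc <- tibble::tibble(
    protein_id = "P1", compartment = "albumen", sample_id = "S1",
    replicate_id = 1:3, batch_id = "MS01",
    concentration = c(10, 12, 14))
  out <- summarize_replicates(conc)
  expect_equal(out$concentration, 12)
  # one measurement per sample: identity
  conc1 <- tibble::tibble(
    protein_id = "P1", compartment = "albumen",
    sample_id = c("S1", "S2"), replicate_id = 1L, batch_id = "MS01",
    concentration = c(3, 8))
  expect_equal(summarize_replicates(conc1)$concentration, c(3, 8))
})

test_that("batch-aware summarisation beats raw means under batch shifts", {
  set.seed(77)
  n_samp <- 12
  rmse_model <- rmse_mean <- numeric(100)
  for (i in 1:100) {
    truth <- rnorm(n_samp, 50, 5)
    batch_eff <- rnorm(4, 0, 6)
    d <- tidyr::crossing(sample_id = sprintf("S%02d", 1:n_samp),
                         replicate_id = 1:2) %>%
      dplyr::mutate(batch_id = sprintf("B%d", sample(1:4, dplyr::n(),
                                                     replace = TRUE)),
                    protein_id = "P1", compartment = "albumen",
                    concentration = truth[as.integer(factor(sample_id))] +
                      batch_eff[as.integer(factor(batch_id))] +
                      rnorm(dplyr::n(), 0, 1))
    est <- summarize_replicates(d)
    means <- d %>% dplyr::group_by(sample_id) %>%
      dplyr::summarise(m = mean(concentration))
    rmse_model[i] <- sqrt(mean((est$concentration - truth)^2))
    rmse_mean[i] <- sqrt(mean((means$m - truth)^2))
  }
  expect_lt(mean(rmse_model), mean(rmse_mean))
})

test_that("MaxQuant-style wide tables reshape to the long format", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "proteinGroups.txt")
  wide <- data.frame(check.names = FALSE,
    `Protein IDs` = c("P1", "P2"),
    `Intensity S1_1` = c(100, 0),
    `Intensity S1_2` = c(150, 30),
    `Intensity S2_1` = c(80, 60))
  utils::write.table(wide, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  long <- read_maxquant(path)
  expect_equal(nrow(long), 6)
  expect_true(is.na(long$intensity[long$protein_id == "P2" &
                                     long$sample_id == "S1" &
                                     long$replicate_id == 1]))
  expect_equal(attr(long, "stage"), "raw")
  flags <- suppressWarnings(flag_identified(long))
  expect_true(flags$identified[flags$protein_id == "P1" &
                                 flags$sample_id == "S1"])
})
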