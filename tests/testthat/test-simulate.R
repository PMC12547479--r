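test_that("generate_plots enumerates the configured strata", {
  cfg <- sim_config(n_regions = 3L, soils_per_region = c(2L, 3L, 6L),
                    plots_per_stratum = 4L)
  plots <- generate_plots(cfg)
  expect_identical(nrow(plots), 44L)
  expect_identical(nrow(enumerate_strata(plots)), 11L)
  expect_identical(plots, generate_plots(cfg))  # same seed, same table

  empty <- generate_plots(sim_config(plots_per_stratum = 0L))
  expect_identical(nrow(empty), 0L)
})

test_that("plot LUI components reproduce the LUI index", {
  plots <- generate_plots(sim_config(plots_per_stratum = 3L))
  comp <- as.matrix(plots[, c("mowing", "fertilisation", "grazing")])
  expect_equal(compute_lui(comp), plots$lui, tolerance = 1e-12)
})

test_that("occupancy matches its closed-form Bernoulli mean in the neutral model", {
  cfg <- sim_config(n_species = 500L, occupancy_logit_mean = 0,
                    occupancy_logit_sd = 0, region_effect_sd = 0,
                    soil_effect_sd = 0, lui_niche_weight = 0,
                    plots_per_stratum = 1L, seed = 11L)
  sim <- simulate_abundances(generate_plots(cfg), cfg)
  pres <- sim$counts > 0L
  n <- length(pres)
  se <- sqrt(0.25 / n)
  expect_lt(abs(mean(pres) - 0.5), 3 * se)
})

test_that("occupancy-abundance coupling yields a positive rank correlation", {
  cfg <- sim_config(n_species = 200L, seed = 5L)
  sim <- simulate_abundances(generate_plots(cfg), cfg)
  occ <- colSums(sim$counts > 0L)
  mean_pos <- apply(sim$counts, 2L, function(x) {
    if (any(x > 0L)) mean(x[x > 0L]) else NA_real_
  })
  keep <- occ > 0L & !is.na(mean_pos)
  rho <- cor(occ[keep], mean_pos[keep], method = "spearman")
  expect_gt(rho, 0)
})

test_that("an empty species pool gives an empty matrix", {
  cfg <- sim_config(n_species = 0L, morphospecies_count = 1L,
                    plots_per_stratum = 2L)
  sim <- simulate_abundances(generate_plots(cfg), cfg)
  expect_identical(ncol(sim$counts), 0L)
})

test_that("morphospecies collapse sums member species and emits pools", {
  # identity mapping: counts unchanged up to column names
  cfg <- sim_config(n_species = 10L, morphospecies_count = 10L,
                    confusable_fraction = 0, plots_per_stratum = 2L)
  sim <- simulate_abundances(generate_plots(cfg), cfg)
  mo <- collapse_to_morphospecies(sim$counts, sim$truth, cfg)
  expect_identical(unname(mo$matrix), unname(sim$counts))
  expect_identical(length(unique(mo$truth$species$morphospecies_id)), 10L)

  # two species with counts 3 and 4 in one sample, same morphospecies
  counts <- matrix(c(3L, 4L), nrow = 1L,
                   dimnames = list("s1", c("sp001", "sp002")))
  cfg2 <- sim_config(n_species = 2L, morphospecies_count = 1L,
                     plots_per_stratum = 1L)
  truth <- simulate_abundances(generate_plots(cfg2), cfg2)$truth
  mo2 <- collapse_to_morphospecies(counts, truth, cfg2)
  expect_identical(as.integer(mo2$matrix[1L, 1L]), 7L)
  expect_identical(mo2$pools$n_total, 7L)
  expect_lte(mo2$pools$n_adult, 7L)

  # matrix column sums equal summed pool totals
  agg <- tapply(mo$pools$n_total, mo$pools$morphospecies_id, sum)
  expect_equal(agg[colnames(mo$matrix)[colSums(mo$matrix) > 0]],
               colSums(mo$matrix)[colSums(mo$matrix) > 0],
               ignore_attr = TRUE)
})

test_that("confusable morphospecies lump two or more species", {
  cfg <- sim_config(confusable_fraction = 0.1, seed = 3L)
  sim <- simulate_abundances(generate_plots(cfg), cfg)
  mo <- collapse_to_morphospecies(sim$counts, sim$truth, cfg)
  sizes <- table(mo$truth$species$morphospecies_id)
  expect_gte(max(sizes), 2L)
  expect_identical(length(sizes), 31L)
})

test_that("reference coverage follows the configured probabilities", {
  cfg <- sim_config(n_species = 200L, seed = 9L)
  sim <- simulate_abundances(generate_plots(cfg), cfg)
  mo <- collapse_to_morphospecies(sim$counts, sim$truth, cfg)

  full <- generate_refdb(mo$truth, p_ref = 1, seed = 1L)
  expect_true(all(full$catalogue$data_type == "genome"))
  expect_identical(nrow(gap_check(full$catalogue$taxon, full$catalogue)), 0L)

  none <- generate_refdb(mo$truth, p_ref = 0, seed = 1L, p_barcode = 0)
  expect_true(all(none$catalogue$data_type == "none"))
  expect_identical(nrow(gap_check(none$catalogue$taxon, none$catalogue)),
                   200L)

  half <- generate_refdb(mo$truth, p_ref = 0.5, seed = 2L)
  gap_frac <- mean(half$catalogue$data_type != "genome")
  expect_lt(abs(gap_frac - 0.5), 3 * sqrt(0.25 / 200))
})

test_that("default calibration reproduces the study's summary structure", {
  rich_all <- c()
  for (s in 1:5) {
    w <- simulate_community(sim_config(seed = s))
    r <- rowSums(w$matrix > 0L)
    rich_all <- c(rich_all, r)
    share <- top_k_share(colSums(w$species_counts), 10L)$share
    expect_gte(share, 0.5)
    expect_lte(share, 0.8)
  }
  expect_gte(mean(rich_all >= 3 & rich_all <= 13), 0.9)
  expect_gte(mean(rich_all), 7)
  expect_lte(mean(rich_all), 10)
})

test_that("regional turnover dominates soil when its knob is high", {
  hits <- 0L
  n_rep <- 25L
  for (s in seq_len(n_rep)) {
    cfg <- sim_config(seed = s, plots_per_stratum = 4L,
                      region_effect_sd = 3, soil_effect_sd = 0.3)
    w <- simulate_community(cfg)
    keep <- rowSums(w$matrix) > 0L
    pt <- permanova(bray_curtis(w$matrix[keep, , drop = FALSE]),
                    w$plots[keep, , drop = FALSE],
                    c("region", "soil_type", "lui"), n_perm = 2L, seed = s)
    hits <- hits + (pt$r2[pt$term == "region"] >
                      pt$r2[pt$term == "soil_type"])
  }
  expect_gte(hits / n_rep, 0.8)
})
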