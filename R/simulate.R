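# Synthetic grassland community generator. Latent species occupy plots via
# a logit-linear niche model (region and soil offsets, a Gaussian land-use
# optimum) and, when present, contribute 1 + negative-binomial individuals
# whose expected abundance rises with the species' base occupancy logit --
# the occupancy-abundance coupling that makes widespread species also
# locally abundant. Species are then collapsed into morphospecies, a few of
# which deliberately lump many confusable species.

#' Configuration of the synthetic community simulator
#'
#' Defaults are calibrated once to the summary structure of the motivating
#' grassland Collembola study: 3 regions with 2, 3 and 6 region-specific
#' soil types (11 strata), per-sample morphospecies richness of roughly
#' 3-13 with a mean near 8.4, the ten most abundant species holding about
#' two thirds of all individuals, regional turnover stronger than soil or
#' land-use effects, and 31 morphospecies over 60 latent species with a few
#' highly confusable lumps.
#'
#' @param n_regions Number of regions.
#' @param soils_per_region Integer vector, number of region-specific soil
#'   types per region (soils are nested in regions).
#' @param plots_per_stratum Plots simulated per region-by-soil stratum.
#' @param n_species Latent species pool size.
#' @param occupancy_logit_mean,occupancy_logit_sd Mean and commonness
#'   gradient of the species' base occupancy logits.
#' @param region_effect_sd,soil_effect_sd Turnover strengths: SDs of the
#'   species-by-region and species-by-soil logit offsets.
#' @param lui_niche_weight Weight of the Gaussian land-use-intensity niche
#'   penalty.
#' @param lui_range Interval of the uniform LUI distribution per plot.
#' @param abundance_intercept,occupancy_abundance_slope Intercept and slope
#'   linking the base occupancy logit to log expected abundance.
#' @param dispersion Negative-binomial dispersion (size) parameter.
#' @param morphospecies_count Number of morphospecies the species map to.
#' @param confusable_fraction Fraction of morphospecies allowed to lump
#'   several species; lump sizes are geometrically skewed so a few
#'   morphospecies hold many species.
#' @param p_adult,p_intact Per-specimen probabilities of being adult and
#'   intact within a pool.
#' @param p_ref Probability that a species already has a reference genome.
#' @param p_barcode Probability that a species without a genome has at
#'   least a barcode.
#' @param seed Master seed for the simulator substreams.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_regions = 3L,
                       soils_per_region = c(2L, 3L, 6L),
                       plots_per_stratum = 12L,
                       n_species = 60L,
                       occupancy_logit_mean = -1.9,
                       occupancy_logit_sd = 1.3,
                       region_effect_sd = 1.2,
                       soil_effect_sd = 0.4,
                       lui_niche_weight = 0.3,
                       lui_range = c(0.5, 3.5),
                       abundance_intercept = 0.7,
                       occupancy_abundance_slope = 1.1,
                       dispersion = 0.7,
                       morphospecies_count = 31L,
                       confusable_fraction = 0.15,
                       p_adult = 0.7,
                       p_intact = 0.9,
                       p_ref = 0.5,
                       p_barcode = 0.3,
                       seed = 1L) {
  stopifnot(
    n_regions >= 1, length(soils_per_region) == n_regions,
    all(soils_per_region >= 1), plots_per_stratum >= 0,
    n_species >= 0, morphospecies_count >= 1,
    confusable_fraction >= 0, confusable_fraction <= 1,
    p_adult >= 0, p_adult <= 1, p_intact >= 0, p_intact <= 1,
    p_ref >= 0, p_ref <= 1, p_barcode >= 0, p_barcode <= 1,
    dispersion > 0, length(lui_range) == 2L, lui_range[1L] <= lui_range[2L]
  )
  cfg <- list(
    n_regions = as.integer(n_regions),
    soils_per_region = as.integer(soils_per_region),
    plots_per_stratum = as.integer(plots_per_stratum),
    n_species = as.integer(n_species),
    occupancy_logit_mean = occupancy_logit_mean,
    occupancy_logit_sd = occupancy_logit_sd,
    region_effect_sd = region_effect_sd,
    soil_effect_sd = soil_effect_sd,
    lui_niche_weight = lui_niche_weight,
    lui_range = lui_range,
    abundance_intercept = abundance_intercept,
    occupancy_abundance_slope = occupancy_abundance_slope,
    dispersion = dispersion,
    morphospecies_count = as.integer(morphospecies_count),
    confusable_fraction = confusable_fraction,
    p_adult = p_adult,
    p_intact = p_intact,
    p_ref = p_ref,
    p_barcode = p_barcode,
    seed = as.integer(seed)
  )
  num <- unlist(cfg[sapply(cfg, is.numeric)])
  if (any(!is.finite(num))) stop("non-finite simulator parameter")
  structure(cfg, class = "sim_config")
}

# Reference means used to decompose a plot's LUI into mowing, fertilisation
# and grazing components (mowing events/y, kg N/ha/y, livestock units/ha/y).
lui_reference_means <- c(mowing = 1.5, fertilisation = 30, grazing = 1)

#' Generate a plot metadata table
#'
#' One row per plot; regions crossed with their region-specific soil types
#' define the strata. LUI is drawn uniformly on `config$lui_range`
#' independently per plot and decomposed into mowing, fertilisation and
#' grazing components such that [compute_lui()] with the packaged reference
#' means reproduces the `lui` column exactly.
#'
#' @param config A [sim_config()].
#' @return Data frame with columns `plot_id`, `region`, `soil_type`, `lui`,
#'   `mowing`, `fertilisation`, `grazing`.
#' @export
generate_plots <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "plots"))
  regions <- sprintf("R%d", seq_len(config$n_regions))
  rows <- list()
  for (r in seq_len(config$n_regions)) {
    for (s in seq_len(config$soils_per_region[r])) {
      n <- config$plots_per_stratum
      if (n == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        region = regions[r],
        soil_type = sprintf("%s_soil%d", regions[r], s),
        lui = runif(n, config$lui_range[1L], config$lui_range[2L]),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(plot_id = character(), region = character(),
                      soil_type = character(), lui = numeric(),
                      mowing = numeric(), fertilisation = numeric(),
                      grazing = numeric(), stringsAsFactors = FALSE))
  }
  plots <- do.call(rbind, rows)
  plots$plot_id <- sprintf("P%03d", seq_len(nrow(plots)))
  # decompose LUI into components: random shares of the standardised sum
  sh <- matrix(rexp(3L * nrow(plots)), ncol = 3L)
  sh <- sh / rowSums(sh)
  comp <- sh * plots$lui * rep(lui_reference_means, each = nrow(plots))
  plots$mowing <- comp[, 1L]
  plots$fertilisation <- comp[, 2L]
  plots$grazing <- comp[, 3L]
  plots[, c("plot_id", "region", "soil_type", "lui", "mowing",
            "fertilisation", "grazing")]
}

#' Simulate latent species abundances across plots
#'
#' Presence of species `i` in plot `j` is Bernoulli with
#' `logit p_ij = mu_i + region_i(j) + soil_i(j) - w (LUI_j - opt_i)^2 / (2 tol_i^2)`
#' and the count given presence is `1 + NegBin(mean = exp(a + b mu_i),
#' size = dispersion)`, so presence guarantees at least one individual and
#' species with high base occupancy are also locally abundant when `b > 0`.
#'
#' @param plots Plot table from [generate_plots()].
#' @param config A [sim_config()].
#' @return List with `counts` (plots x species integer matrix) and `truth`,
#'   a `sim_truth` object holding per-species niche parameters.
#' @export
simulate_abundances <- function(plots, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(plots) == 0L) stop("plot table is empty")
  set.seed(stage_seed(config$seed, "abundances"))
  S <- config$n_species
  species <- if (S > 0L) sprintf("sp%03d", seq_len(S)) else character()
  regions <- sort(unique(plots$region))
  soils <- sort(unique(plots$soil_type))
  mu <- rnorm(S, config$occupancy_logit_mean, config$occupancy_logit_sd)
  reg_eff <- matrix(rnorm(S * length(regions), 0, config$region_effect_sd),
                    nrow = S, ncol = length(regions),
                    dimnames = list(species, regions))
  soil_eff <- matrix(rnorm(S * length(soils), 0, config$soil_effect_sd),
                     nrow = S, ncol = length(soils),
                     dimnames = list(species, soils))
  opt <- runif(S, config$lui_range[1L], config$lui_range[2L])
  tol <- runif(S, 0.5, 1.5)
  counts <- matrix(0L, nrow = nrow(plots), ncol = S,
                   dimnames = list(plots$plot_id, species))
  if (S > 0L) {
    mean_abund <- exp(config$abundance_intercept +
                        config$occupancy_abundance_slope * mu)
    for (j in seq_len(nrow(plots))) {
      eta <- mu + reg_eff[, plots$region[j]] + soil_eff[, plots$soil_type[j]] -
        config$lui_niche_weight * (plots$lui[j] - opt)^2 / (2 * tol^2)
      pres <- rbinom(S, 1L, stats::plogis(eta))
      n <- pres * (1L + rnbinom(S, size = config$dispersion, mu = mean_abund))
      counts[j, ] <- as.integer(n)
    }
  }
  truth <- structure(
    list(
      species = data.frame(species = species, mu = mu, lui_optimum = opt,
                           lui_tolerance = tol,
                           morphospecies_id = rep(NA_character_, S),
                           has_reference = rep(NA, S),
                           stringsAsFactors = FALSE),
      region_effects = reg_eff,
      soil_effects = soil_eff,
      config = config
    ),
    class = "sim_truth"
  )
  list(counts = counts, truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("Latent community truth: %d species", nrow(x$species)))
  if (!all(is.na(x$species$morphospecies_id))) {
    cat(sprintf(" in %d morphospecies",
                length(unique(x$species$morphospecies_id))))
  }
  cat("\n")
  invisible(x)
}

# Skewed allocation of species to morphospecies: every morphospecies holds
# at least one species; the surplus goes to a confusable subset with
# geometric weights so a few lumps are large.
assign_morphospecies <- function(S, M, confusable_fraction) {
  if (S < M) stop("morphospecies_count must not exceed n_species")
  morph_ids <- sprintf("m%02d", seq_len(M))
  map <- morph_ids[seq_len(min(S, M))]
  extra <- S - M
  if (extra > 0L) {
    n_conf <- max(1L, round(confusable_fraction * M))
    conf <- morph_ids[seq_len(n_conf)]
    w <- 0.5^(seq_len(n_conf) - 1L)
    map <- c(map, conf[sample.int(n_conf, extra, replace = TRUE,
                                  prob = w / sum(w))])
  }
  map
}

#' Collapse a species matrix into morphospecies observations
#'
#' Sums member-species counts per sample into a morphospecies-by-sample
#' matrix and emits one pool row per non-empty cell, with adult and intact
#' specimen numbers drawn binomially from the pool total. A configured
#' fraction of morphospecies are confusable lumps holding two or more
#' species.
#'
#' @param species_counts Plots x species integer matrix from
#'   [simulate_abundances()].
#' @param truth The matching `sim_truth`; its species table gains the
#'   morphospecies assignment.
#' @param config A [sim_config()].
#' @return List with `matrix` (samples x morphospecies), `pools` (data
#'   frame) and the updated `truth`.
#' @export
collapse_to_morphospecies <- function(species_counts, truth,
                                      config = sim_config()) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "morphospecies"))
  S <- ncol(species_counts)
  map <- assign_morphospecies(S, config$morphospecies_count,
                              config$confusable_fraction)
  if (length(map) != S || anyNA(map)) stop("species without morphospecies assignment")
  truth$species$morphospecies_id <- map
  morph_ids <- sort(unique(map))
  mm <- matrix(0L, nrow = nrow(species_counts), ncol = length(morph_ids),
               dimnames = list(rownames(species_counts), morph_ids))
  for (m in morph_ids) {
    mm[, m] <- as.integer(rowSums(species_counts[, map == m, drop = FALSE]))
  }
  nz <- which(mm > 0L, arr.ind = TRUE)
  nz <- nz[order(nz[, 1L], nz[, 2L]), , drop = FALSE]
  n_total <- mm[nz]
  pools <- data.frame(
    sample_id = rownames(mm)[nz[, 1L]],
    morphospecies_id = colnames(mm)[nz[, 2L]],
    n_total = as.integer(n_total),
    n_adult = rbinom(length(n_total), n_total, config$p_adult),
    n_intact = rbinom(length(n_total), n_total, config$p_intact),
    stringsAsFactors = FALSE
  )
  list(matrix = mm, pools = pools, truth = truth)
}

#' Generate a synthetic reference-database catalogue
#'
#' Flags each latent species as having a reference genome (probability
#' `p_ref`), otherwise a barcode (probability `p_barcode`), otherwise
#' nothing, and writes synthetic accessions for covered species.
#'
#' @param truth A `sim_truth` object.
#' @param p_ref Probability of an existing genome.
#' @param seed Seed for this stage.
#' @param p_barcode Probability of a barcode among genome-less species.
#' @return List with `catalogue` (data frame: taxon, data_type, accession)
#'   and the updated `truth` (`has_reference` = genome available).
#' @export
generate_refdb <- function(truth, p_ref = 0.5, seed = 1L, p_barcode = 0.3) {
  stopifnot(inherits(truth, "sim_truth"), p_ref >= 0, p_ref <= 1)
  set.seed(stage_seed(seed, "refdb"))
  sp <- truth$species$species
  genome <- runif(length(sp)) < p_ref
  barcode <- !genome & runif(length(sp)) < p_barcode
  data_type <- ifelse(genome, "genome", ifelse(barcode, "barcode", "none"))
  catalogue <- data.frame(
    taxon = sp,
    data_type = data_type,
    accession = ifelse(data_type == "none", "",
                       sprintf("SYN%06d", seq_along(sp))),
    stringsAsFactors = FALSE
  )
  truth$species$has_reference <- genome
  list(catalogue = catalogue, truth = truth)
}

#' Simulate a full synthetic study
#'
#' Runs [generate_plots()], [simulate_abundances()],
#' [collapse_to_morphospecies()] and [generate_refdb()] under one seeded
#' configuration.
#'
#' @param config A [sim_config()].
#' @return List with `plots`, `species_counts`, `matrix`, `pools`,
#'   `catalogue` and `truth`.
#' @export
simulate_community <- function(config = sim_config()) {
  plots <- generate_plots(config)
  ab <- simulate_abundances(plots, config)
  mo <- collapse_to_morphospecies(ab$counts, ab$truth, config)
  db <- generate_refdb(mo$truth, p_ref = config$p_ref, seed = config$seed,
                       p_barcode = config$p_barcode)
  list(plots = plots, species_counts = ab$counts, matrix = mo$matrix,
       pools = mo$pools, catalogue = db$catalogue, truth = db$truth)
}

#' Species composition of every morphospecies pool
#'
#' Expands the latent species matrix into long form: one row per
#' (sample, morphospecies, species) with a positive count. This is the
#' ground truth the identification scheduler samples from in simulation
#' mode.
#'
#' @param species_counts Plots x species matrix.
#' @param truth `sim_truth` with morphospecies assignments.
#' @return Data frame with columns `sample_id`, `morphospecies_id`,
#'   `species`, `count`.
#' @export
pool_composition <- function(species_counts, truth) {
  stopifnot(inherits(truth, "sim_truth"))
  map <- truth$species$morphospecies_id
  if (anyNA(map)) stop("truth has no morphospecies assignment yet")
  nz <- which(species_counts > 0L, arr.ind = TRUE)
  out <- data.frame(
    sample_id = rownames(species_counts)[nz[, 1L]],
    morphospecies_id = map[nz[, 2L]],
    species = colnames(species_counts)[nz[, 2L]],
    count = as.integer(species_counts[nz]),
    stringsAsFactors = FALSE
  )
  out[order(out$sample_id, out$morphospecies_id, out$species), ,
      drop = FALSE]
}
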