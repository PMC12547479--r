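test_that("habitat distance counts differing stratifying variables", {
  meta <- toy_schedule_metadata()
  a <- meta[1L, ]; b <- meta[2L, ]; c_ <- meta[3L, ]
  expect_identical(habitat_distance(a, a), 0L)
  expect_identical(habitat_distance(a, b), 3L)
  expect_identical(habitat_distance(b, c_), 2L)
  expect_identical(habitat_distance(a, c_), habitat_distance(c_, a))
  expect_error(habitat_distance(a[, 1:2], b), "missing")
})

test_that("visits start at the adult-richest pool and spread maximin", {
  meta <- toy_schedule_metadata()
  pools <- data.frame(
    sample_id = c("s1", "s2", "s3"), morphospecies_id = "mA",
    n_total = c(10L, 5L, 5L), n_adult = c(8L, 4L, 4L),
    n_intact = c(9L, 4L, 4L), stringsAsFactors = FALSE)
  ord <- order_visits("mA", pools, meta)
  expect_identical(ord$sample_id, c("s1", "s2", "s3"))

  # independent oracle: greedy farthest-point orders from the fixed start
  d <- matrix(c(0, 3, 1, 3, 0, 2, 1, 2, 0), 3L,
              dimnames = list(meta$plot_id, meta$plot_id))
  oracle <- maximin_orders(d, first = 1L)
  expect_true(list(match(ord$sample_id, meta$plot_id)) %in% oracle)

  single <- order_visits("mA", pools[2L, ], meta)
  expect_identical(single$sample_id, "s2")
  expect_error(order_visits("mB", pools, meta), "no pools")

  # the adult+intact maximum picks the first visit
  pools2 <- pools; pools2$n_adult <- c(2L, 10L, 2L)
  pools2$n_intact <- c(2L, 9L, 2L)
  expect_identical(order_visits("mA", pools2, meta)$sample_id[1L], "s2")
})

test_that("the second visit is farthest from the first on exhaustive cases", {
  # all 8 habitat combinations of 2 regions x 2 soils x 2 LUI classes
  grid <- expand.grid(region = c("R1", "R2"), soil_type = c("a", "b"),
                      lui_class = c("low", "high"),
                      stringsAsFactors = FALSE)
  set.seed(1)
  for (rep in 1:10) {
    idx <- sample(8L, 4L)
    meta <- cbind(plot_id = paste0("s", 1:4), grid[idx, ])
    pools <- data.frame(sample_id = meta$plot_id, morphospecies_id = "m",
                        n_total = 5L, n_adult = 5L, n_intact = 5L,
                        stringsAsFactors = FALSE)
    ord <- order_visits("m", pools, meta,
                        variables = c("region", "soil_type", "lui_class"))
    d <- matrix(0L, 4L, 4L, dimnames = list(meta$plot_id, meta$plot_id))
    for (v in c("region", "soil_type", "lui_class")) {
      d <- d + outer(meta[[v]], meta[[v]], "!=")
    }
    first <- ord$sample_id[1L]
    second <- ord$sample_id[2L]
    expect_identical(d[first, second], max(d[first, ]))
  }
})

test_that("identification reveals species and obeys the stop rules", {
  meta <- toy_schedule_metadata()
  pools <- data.frame(
    sample_id = c("s1", "s2"), morphospecies_id = "mA",
    n_total = c(3L, 3L), n_adult = c(3L, 3L), n_intact = c(3L, 3L),
    stringsAsFactors = FALSE)
  comp <- data.frame(
    sample_id = c("s1", "s2"), morphospecies_id = "mA",
    species = "sp1", count = c(3L, 3L), stringsAsFactors = FALSE)
  pt <- build_priority_table(matrix(c(3L, 3L), 2L, 1L,
                                    dimnames = list(c("s1", "s2"), "mA")))
  pt$selected <- TRUE

  # single pool, budget 1: one specimen, one species
  run1 <- run_identification(pt, pools[1L, ], meta, comp,
                             per_visit_budget = 1L)
  expect_identical(run1$taxa$taxon, "sp1")
  expect_identical(run1$ledger$specimens_prepared, 1L)

  # both pools hold the same species: stops after visit 2 (nothing new),
  # with both visits ledgered
  run2 <- run_identification(pt, pools, meta, comp,
                             per_visit_budget = Inf)
  expect_identical(nrow(run2$visits), 2L)
  expect_identical(run2$visits$n_new_species, c(1L, 0L))
  expect_identical(run2$ledger$specimens_prepared, 6L)
})

test_that("replaying the fixture's most speciose morphospecies reveals 7 taxa", {
  tab <- load_table1_fixture()
  members <- tab$taxon[tab$morphospecies_id == "A"]
  comp <- data.frame(sample_id = "s1", morphospecies_id = "A",
                     species = members, count = 2L,
                     stringsAsFactors = FALSE)
  pools <- data.frame(sample_id = "s1", morphospecies_id = "A",
                      n_total = sum(comp$count),
                      n_adult = sum(comp$count),
                      n_intact = sum(comp$count), stringsAsFactors = FALSE)
  meta <- data.frame(plot_id = "s1", region = "R1", soil_type = "a",
                     lui_class = "low", stringsAsFactors = FALSE)
  pt <- build_priority_table(matrix(sum(comp$count), 1L, 1L,
                                    dimnames = list("s1", "A")))
  pt$selected <- TRUE
  run <- run_identification(pt, pools, meta, comp, per_visit_budget = Inf)
  expect_identical(nrow(run$taxa), 7L)
  expect_setequal(run$taxa$taxon, members)
})

test_that("with stop rules off the scheduler recovers the brute-force union", {
  for (s in 1:5) {
    cfg <- sim_config(seed = s, plots_per_stratum = 1L, n_species = 20L,
                      morphospecies_count = 8L, p_adult = 1)
    w <- simulate_community(cfg)
    # make every specimen adult so the latent union is fully reachable
    w$pools$n_adult <- w$pools$n_total
    comp <- pool_composition(w$species_counts, w$truth)
    pt <- build_priority_table(w$matrix)
    pt$selected <- pt$occupancy > 0L
    run <- run_identification(pt, w$pools, w$plots, comp,
                              per_visit_budget = Inf,
                              stop_no_new = FALSE, stop_singletons = FALSE,
                              seed = s)
    sel_m <- pt$morphospecies_id[pt$selected]
    oracle <- sort(unique(comp$species[comp$morphospecies_id %in% sel_m]))
    expect_identical(run$taxa$taxon, oracle)
  }
})

test_that("effort respects the capacity budget and budgets are monotone", {
  cfg <- sim_config(seed = 2L, plots_per_stratum = 2L, n_species = 30L,
                    morphospecies_count = 12L)
  w <- simulate_community(cfg)
  comp <- pool_composition(w$species_counts, w$truth)
  pt <- apply_stop_rule(flag_local_abundance(build_priority_table(w$matrix)),
                        min_occupancy = 1L)
  run <- run_identification(pt, w$pools, w$plots, comp,
                            per_visit_budget = 3L, capacity_budget = 10L,
                            seed = 1L)
  expect_lte(run$ledger$specimens_prepared, 10L)
  expect_identical(run$ledger$total_effort, run$ledger$specimens_prepared)

  prev <- -1L
  for (budget in c(1L, 2L, 4L, 8L)) {
    r <- run_identification(pt, w$pools, w$plots, comp,
                            per_visit_budget = budget, seed = 1L)
    expect_gte(nrow(r$taxa), prev)
    prev <- nrow(r$taxa)
  }
  expect_error(run_identification(pt, w$pools, w$plots, comp,
                                  per_visit_budget = -1L), "budget")
})
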