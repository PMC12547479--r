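# End-to-end pipeline over a simulated study: stratify -> prioritise ->
# schedule/identify -> gap-check -> benchmark against the latent truth.

#' Run the whole workflow on a simulated community
#'
#' Simulates a study under `sim`, selects the habitat-stratified sample
#' subset, builds and truncates the morphospecies priority table, runs the
#' identification scheduler against the latent truth, checks identified
#' species against the synthetic reference catalogue, and benchmarks the
#' recovered species list against the full latent community (taxon
#' overlap, individual coverage, effort ratio, top-10 concentration,
#' coverage-effort curve). All randomness flows from `config$seed` through
#' named substreams, so identical seed and inputs give identical outputs.
#'
#' @param config A [run_config()].
#' @param sim A [sim_config()]; defaults to the standard simulator
#'   calibration with the run seed.
#' @param out_dir Optional directory; when given, all intermediate tables
#'   are written there as tab-separated text.
#' @return List of class `strataseq_report` with elements `config`, `sim`,
#'   `selection`, `samples`, `priority`, `identification`, `ledger`,
#'   `tasks`, `benchmark`, `curve` and `truth`.
#' @export
run_pipeline <- function(config = run_config(), sim = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(sim)) sim <- sim_config(seed = config$seed)
  stage <- "simulate"
  report <- tryCatch({
    world <- simulate_community(sim)

    stage <- "stratify"
    selection <- select_subset(world$plots, config$stratify_vars,
                               scope = config$lui_quartile_scope,
                               seed = stage_seed(config$seed, "stratify"))
    samples <- selected_samples(selection)
    sub_matrix <- world$matrix[samples, , drop = FALSE]
    sub_pools <- world$pools[world$pools$sample_id %in% samples, ,
                             drop = FALSE]

    stage <- "prioritize"
    priority <- build_priority_table(sub_matrix)
    priority <- flag_local_abundance(priority, config$flag_occupancy_cutoff,
                                     config$local_abundance_flag_threshold)
    priority <- apply_stop_rule(priority, config$stop_rule_min_occupancy,
                                config$capacity_budget, sub_pools,
                                config$prep_per_pool)

    stage <- "schedule"
    composition <- pool_composition(world$species_counts, world$truth)
    composition <- composition[composition$sample_id %in% samples, ,
                               drop = FALSE]
    metadata <- world$plots[world$plots$plot_id %in% samples, ,
                            drop = FALSE]
    ident <- run_identification(
      priority, sub_pools, metadata, composition,
      per_visit_budget = config$per_visit_budget,
      capacity_budget = config$capacity_budget,
      seed = stage_seed(config$seed, "identify"))

    stage <- "gapcheck"
    tasks <- gap_check(merge_priority_rank(ident$taxa, composition,
                                           priority),
                       world$catalogue, required = "genome")
    ledger <- effort_ledger(ident$ledger$specimens_prepared,
                            sum(tasks$n_specimens_designated))

    stage <- "benchmark"
    latent <- data.frame(
      taxon = colnames(world$species_counts),
      taxon_rank = "species",
      count = as.integer(colSums(world$species_counts)),
      stringsAsFactors = FALSE)
    latent <- latent[latent$count > 0L, , drop = FALSE]
    match <- match_taxa(ident$taxa, latent, mode = config$match_mode)
    coverage <- individual_coverage(ident$taxa$taxon, latent)
    top10 <- top_k_share(setNames(latent$count, latent$taxon), 10L)
    eff <- effort_ratio(max(ledger$total_effort, 0L) + 0,
                        max(sum(world$species_counts), 1L))
    curve <- coverage_effort_curve(ident$stream, latent)

    list(config = config, sim = sim, selection = selection,
         samples = samples, matrix = sub_matrix, priority = priority,
         identification = ident, ledger = ledger, tasks = tasks,
         benchmark = list(match = match, individual_coverage = coverage,
                          top10 = top10, effort_ratio = eff,
                          benchmark_taxa = latent),
         curve = curve, truth = world$truth, world = world)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  class(report) <- "strataseq_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# attach priority rank to an identified taxon list so sequencing tasks can
# be ordered by the rank of the morphospecies a species was found in
merge_priority_rank <- function(taxa, composition, priority) {
  if (nrow(taxa) == 0L) return(taxa)
  first_morph <- vapply(taxa$taxon, function(sp) {
    m <- composition$morphospecies_id[composition$species == sp]
    if (length(m) == 0L) NA_character_ else sort(m)[1L]
  }, character(1L))
  rank <- priority$rank[match(first_morph, priority$morphospecies_id)]
  out <- taxa
  out$morphospecies_id <- first_morph
  out[order(rank, out$taxon, na.last = TRUE), , drop = FALSE]
}

# write every intermediate table of a report as tab-separated text
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- report$world
  write_table(w$plots, file.path(out_dir, "plots.tsv"))
  write_morph_matrix(w$matrix, file.path(out_dir, "morph_matrix.tsv"))
  write_table(w$pools, file.path(out_dir, "pools.tsv"))
  write_table(w$catalogue, file.path(out_dir, "refdb.tsv"))
  write_table(w$truth$species, file.path(out_dir, "truth.tsv"))
  write_table(as.data.frame(report$selection),
              file.path(out_dir, "subset.tsv"))
  write_table(as.data.frame(report$priority),
              file.path(out_dir, "priority.tsv"))
  write_table(report$identification$visits,
              file.path(out_dir, "schedule.tsv"))
  write_table(report$identification$revealed,
              file.path(out_dir, "outcomes.tsv"))
  write_table(as.data.frame(report$tasks), file.path(out_dir, "tasks.tsv"))
  write_table(report$curve, file.path(out_dir, "coverage_curve.tsv"))
  summary_df <- data.frame(
    key = c("seed", "n_samples", "n_selected_morphospecies",
            "specimens_prepared", "specimens_designated", "total_effort",
            "taxa_identified", "individual_coverage", "effort_ratio"),
    value = c(report$config$seed, length(report$samples),
              sum(report$priority$selected),
              report$ledger$specimens_prepared,
              report$ledger$specimens_designated_for_sequencing,
              report$ledger$total_effort,
              nrow(report$identification$taxa),
              as.numeric(report$benchmark$individual_coverage),
              report$benchmark$effort_ratio),
    stringsAsFactors = FALSE
  )
  write_table(summary_df, file.path(out_dir, "summary.tsv"))
  invisible(out_dir)
}

#' @export
print.strataseq_report <- function(x, ...) {
  cat("Workflow report\n")
  cat(sprintf("  %d samples in the habitat-stratified subset (%d strata)\n",
              length(x$samples), nrow(x$selection)))
  cat(sprintf("  %d of %d morphospecies selected for identification\n",
              sum(x$priority$selected), nrow(x$priority)))
  print(x$ledger)
  cat(sprintf("  %d taxa identified; individual coverage %.1f%% at %.1f%% of exhaustive effort\n",
              nrow(x$identification$taxa),
              100 * as.numeric(x$benchmark$individual_coverage),
              100 * x$benchmark$effort_ratio))
  cat(sprintf("  %d reference-database gaps -> sequencing tasks\n",
              nrow(x$tasks)))
  invisible(x)
}
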