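#' Run configuration for the workflow
#'
#' Collects the tunable constants of a workflow run in one validated list.
#' Defaults follow the published study design: morphospecies are selected
#' for detailed identification when they occur in *more than*
#' `stop_rule_min_occupancy` samples (an exclusive bound), permutation tests
#' use 999 iterations, and land-use-intensity quartiles are taken within
#' each region-by-soil stratum.
#'
#' @param seed Non-negative integer master seed. Every stage derives its own
#'   substream from it via [stage_seed()], so stages can be re-run
#'   independently and reproducibly.
#' @param stratify_vars Ordered character vector of stratifying columns in
#'   the plot table.
#' @param lui_quartile_scope Where LUI quartiles are computed: `"stratum"`
#'   (within each region-by-soil combination) or `"region"`.
#' @param stop_rule_min_occupancy Exclusive occupancy bound of the
#'   stop-rule; a morphospecies passes when occupancy is strictly greater.
#' @param flag_occupancy_cutoff Maximum occupancy for a morphospecies to be
#'   eligible for the local-abundance flag ("a single or very few samples").
#' @param local_abundance_flag_threshold Minimum within-sample abundance
#'   that flags a rare-but-locally-abundant morphospecies. The one such case
#'   in the motivating study had 19 specimens; the default of 15 is a
#'   configuration choice, not an empirical constant.
#' @param capacity_budget Total specimen-preparation capacity (integer) or
#'   `Inf` for unlimited.
#' @param per_visit_budget Specimens prepared per pool visit.
#' @param prep_per_pool Projected preparation allotment per visited pool
#'   used when costing the stop-rule truncation.
#' @param n_permutations Permutations for PERMANOVA.
#' @param nmds_dimensions,nmds_restarts NMDS embedding dimension and number
#'   of random restarts.
#' @param match_mode Taxon matching mode, `"exact_label"` or
#'   `"genus_rollup"`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       stratify_vars = c("region", "soil_type"),
                       lui_quartile_scope = c("stratum", "region"),
                       stop_rule_min_occupancy = 3L,
                       flag_occupancy_cutoff = 1L,
                       local_abundance_flag_threshold = 15L,
                       capacity_budget = Inf,
                       per_visit_budget = 3L,
                       prep_per_pool = 3L,
                       n_permutations = 999L,
                       nmds_dimensions = 2L,
                       nmds_restarts = 20L,
                       match_mode = c("exact_label", "genus_rollup")) {
  lui_quartile_scope <- match.arg(lui_quartile_scope)
  match_mode <- match.arg(match_mode)
  stopifnot(
    is.numeric(seed), length(seed) == 1L, seed >= 0, seed == floor(seed),
    is.character(stratify_vars), length(stratify_vars) >= 1L,
    stop_rule_min_occupancy >= 0,
    local_abundance_flag_threshold >= 0,
    capacity_budget >= 0,
    n_permutations >= 1,
    nmds_dimensions >= 1
  )
  structure(
    list(
      seed = as.integer(seed),
      stratify_vars = stratify_vars,
      lui_quartile_scope = lui_quartile_scope,
      stop_rule_min_occupancy = as.integer(stop_rule_min_occupancy),
      flag_occupancy_cutoff = as.integer(flag_occupancy_cutoff),
      local_abundance_flag_threshold =
        as.integer(local_abundance_flag_threshold),
      capacity_budget = capacity_budget,
      per_visit_budget = as.integer(per_visit_budget),
      prep_per_pool = as.integer(prep_per_pool),
      n_permutations = as.integer(n_permutations),
      nmds_dimensions = as.integer(nmds_dimensions),
      nmds_restarts = as.integer(nmds_restarts),
      match_mode = match_mode
    ),
    class = "run_config"
  )
}

#' Derive a named seed substream
#'
#' Maps a master seed and a stage label to a deterministic integer seed
#' below 2^31, so that each workflow stage consumes its own random stream
#' and stages can be re-run in isolation without disturbing one another.
#'
#' @param seed Master seed (non-negative integer).
#' @param stage Character label of the stage.
#' @return An integer seed.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0,
            is.character(stage), length(stage) == 1L)
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 1000003
  as.integer((as.numeric(seed) %% 2147483647 * 1009 + h) %% 2147483647)
}

#' @export
print.run_config <- function(x, ...) {
  cat("Workflow run configuration\n")
  cat("  seed:", x$seed, "\n")
  cat("  stratify by:", paste(x$stratify_vars, collapse = ", "),
      sprintf("(LUI quartiles per %s)\n", x$lui_quartile_scope))
  cat(sprintf("  stop-rule: occupancy > %d, flag if occupancy <= %d and max abundance >= %d\n",
              x$stop_rule_min_occupancy, x$flag_occupancy_cutoff,
              x$local_abundance_flag_threshold))
  cat(sprintf("  budgets: capacity %s, %d specimens/visit, %d allotted/pool\n",
              if (is.finite(x$capacity_budget)) x$capacity_budget else "unlimited",
              x$per_visit_budget, x$prep_per_pool))
  cat(sprintf("  stats: %d permutations, NMDS k=%d (%d restarts), match mode %s\n",
              x$n_permutations, x$nmds_dimensions, x$nmds_restarts,
              x$match_mode))
  invisible(x)
}
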