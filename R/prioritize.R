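# Morphospecies prioritisation: occupancy ranking with abundance
# tie-breaks, local-abundance flags for rare-but-abundant morphospecies,
# and the stop-rule that decides which morphospecies get detailed
# identification.

#' Build the morphospecies priority table
#'
#' Commonness is operationalised strictly as occupancy — the number of
#' subset samples a morphospecies is present in. Entries are sorted by
#' occupancy (descending), then total abundance (descending), then
#' morphospecies id (ascending, for determinism), and ranked by position.
#'
#' @param mat Samples x morphospecies integer matrix.
#' @return Data frame of class `priority_table` with columns
#'   `morphospecies_id`, `occupancy`, `total_abundance`,
#'   `max_sample_abundance`, `flagged`, `rank`, `selected`.
#' @export
build_priority_table <- function(mat) {
  if (any(mat < 0)) stop("negative count in morphospecies matrix")
  occupancy <- colSums(mat > 0L)
  total <- colSums(mat)
  maxs <- if (nrow(mat) > 0L) apply(mat, 2L, max) else rep(0L, ncol(mat))
  ids <- colnames(mat)
  ord <- order(-occupancy, -total, ids, method = "radix")
  out <- data.frame(
    morphospecies_id = ids[ord],
    occupancy = as.integer(occupancy[ord]),
    total_abundance = as.integer(total[ord]),
    max_sample_abundance = as.integer(maxs[ord]),
    flagged = FALSE,
    rank = seq_along(ord),
    selected = FALSE,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("priority_table", "data.frame")
  out
}

#' Flag rare but locally abundant morphospecies
#'
#' A morphospecies of remarkably high abundance within a single or very few
#' samples is marked so it can be pulled forward when identification
#' capacity allows rarer taxa: flagged iff
#' `occupancy <= occupancy_cutoff` and
#' `max_sample_abundance >= abundance_threshold`.
#'
#' @param entries A `priority_table`.
#' @param occupancy_cutoff Maximum occupancy for eligibility.
#' @param abundance_threshold Minimum within-sample abundance.
#' @return The table with its `flagged` column set.
#' @export
flag_local_abundance <- function(entries, occupancy_cutoff = 1L,
                                 abundance_threshold = 15L) {
  stopifnot(inherits(entries, "priority_table"),
            occupancy_cutoff >= 0, abundance_threshold >= 0)
  entries$flagged <- entries$occupancy <= occupancy_cutoff &
    entries$max_sample_abundance >= abundance_threshold
  entries
}

#' Apply the stop-rule to select morphospecies for identification
#'
#' A morphospecies is a candidate when its occupancy strictly exceeds
#' `min_occupancy` or it carries the local-abundance flag. Candidates are
#' taken in rank order — threshold-passing entries first, flagged-only
#' entries appended after them — and truncated so the projected
#' specimen-preparation effort stays within `capacity_budget`. The
#' projected effort of a morphospecies is the sum over its pools of
#' `min(prep_per_pool, n_adult)` when a pools table is supplied, otherwise
#' `prep_per_pool` per occupied sample.
#'
#' @param entries A `priority_table` (ranked).
#' @param min_occupancy Exclusive occupancy bound (default 3: "more than
#'   three samples").
#' @param capacity_budget Total preparation capacity, or `Inf`.
#' @param pools Optional pools table with `morphospecies_id` and `n_adult`.
#' @param prep_per_pool Preparation allotment per visited pool.
#' @return The table with its `selected` column set; the projected effort
#'   of the selection is in the `projected_effort` attribute.
#' @export
apply_stop_rule <- function(entries, min_occupancy = 3L,
                            capacity_budget = Inf, pools = NULL,
                            prep_per_pool = 3L) {
  stopifnot(inherits(entries, "priority_table"), min_occupancy >= 0,
            capacity_budget >= 0, prep_per_pool >= 0)
  cost_of <- function(id, occupancy) {
    if (is.null(pools)) return(prep_per_pool * occupancy)
    p <- pools[pools$morphospecies_id == id & pools$n_total > 0L, ,
               drop = FALSE]
    sum(pmin(prep_per_pool, p$n_adult))
  }
  by_threshold <- entries$occupancy > min_occupancy
  flagged_only <- entries$flagged & !by_threshold
  candidates <- c(entries$rank[by_threshold], entries$rank[flagged_only])
  selected <- logical(nrow(entries))
  effort <- 0
  for (r in candidates) {
    i <- which(entries$rank == r)
    cost <- cost_of(entries$morphospecies_id[i], entries$occupancy[i])
    if (effort + cost > capacity_budget) break
    selected[i] <- TRUE
    effort <- effort + cost
  }
  entries$selected <- selected
  attr(entries, "projected_effort") <- effort
  entries
}

#' @export
print.priority_table <- function(x, ...) {
  cat(sprintf(
    "Morphospecies priority table: %d morphospecies, %d flagged, %d selected\n",
    nrow(x), sum(x$flagged), sum(x$selected)))
  print.data.frame(as.data.frame(x))
  invisible(x)
}
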