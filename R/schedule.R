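# Identification scheduling: order the pools of each selected
# morphospecies across maximally distinct habitats (farthest-point
# ordering under Hamming distance on the stratifying variables), then
# simulate or replay specimen-by-specimen identification with the
# stop-rules and an effort ledger.

#' Habitat distinctness between two samples
#'
#' Counts the stratifying variables on which two samples differ (Hamming
#' distance). LUI should be recoded to a high/low class with [lui_class()]
#' before use, so that all variables are categorical.
#'
#' @param sample_a,sample_b One-row data frames (or named lists) holding
#'   values for all `variables`.
#' @param variables Character vector of stratifying variables.
#' @return Integer distance in `0..length(variables)`.
#' @export
habitat_distance <- function(sample_a, sample_b,
                             variables = c("region", "soil_type",
                                           "lui_class")) {
  for (v in variables) {
    if (is.null(sample_a[[v]]) || is.null(sample_b[[v]]) ||
        is.na(sample_a[[v]]) || is.na(sample_b[[v]])) {
      stop("missing stratifying variable: ", v)
    }
  }
  sum(vapply(variables,
             function(v) sample_a[[v]] != sample_b[[v]], logical(1L)))
}

# Pairwise habitat distances for a metadata table; adds lui_class from lui
# (recoded against the table's own mean) when absent.
habitat_distance_matrix <- function(metadata,
                                    variables = c("region", "soil_type",
                                                  "lui_class")) {
  if ("lui_class" %in% variables && !"lui_class" %in% names(metadata)) {
    if (!"lui" %in% names(metadata)) stop("missing stratifying variable: lui_class")
    metadata$lui_class <- lui_class(metadata$lui)
  }
  n <- nrow(metadata)
  d <- matrix(0L, n, n, dimnames = list(metadata$plot_id, metadata$plot_id))
  for (v in variables) {
    if (!v %in% names(metadata)) stop("missing stratifying variable: ", v)
    d <- d + outer(metadata[[v]], metadata[[v]], "!=")
  }
  d
}

#' Order identification visits for one morphospecies
#'
#' The first visit goes to the pool with the most adult plus intact
#' specimens (ties: larger total, then sample id). Each subsequent visit
#' maximises the minimum habitat distance to all already-ordered samples
#' (farthest-point ordering), with ties broken by larger pool total, then
#' sample id.
#'
#' @param morphospecies_id The morphospecies to schedule.
#' @param pools Pools table (`sample_id`, `morphospecies_id`, `n_total`,
#'   `n_adult`, `n_intact`).
#' @param metadata Sample metadata with `plot_id`, the stratifying
#'   variables and `lui` (for the high/low recoding).
#' @param variables Stratifying variables used for distinctness.
#' @return Data frame of the morphospecies' pools in visit order, with a
#'   `visit` column.
#' @export
order_visits <- function(morphospecies_id, pools, metadata,
                         variables = c("region", "soil_type", "lui_class")) {
  p <- pools[pools$morphospecies_id == morphospecies_id, , drop = FALSE]
  if (nrow(p) == 0L) stop("no pools for morphospecies ", morphospecies_id)
  meta <- metadata[match(p$sample_id, metadata$plot_id), , drop = FALSE]
  if (anyNA(meta$plot_id)) stop("pool sample missing from metadata")
  dmat <- habitat_distance_matrix(metadata, variables)
  d <- dmat[p$sample_id, p$sample_id, drop = FALSE]
  n <- nrow(p)
  avail <- best_first(p)
  ordered <- avail[1L]
  remaining <- setdiff(seq_len(n), ordered)
  while (length(remaining) > 0L) {
    mind <- vapply(remaining, function(i) min(d[i, ordered]), numeric(1L))
    cand <- remaining[mind == max(mind)]
    cand <- cand[order(-p$n_total[cand], p$sample_id[cand],
                       method = "radix")]
    ordered <- c(ordered, cand[1L])
    remaining <- setdiff(remaining, cand[1L])
  }
  out <- p[ordered, , drop = FALSE]
  out$visit <- seq_len(n)
  rownames(out) <- NULL
  out
}

# index of the starting pool: max adult+intact, tie max total, tie id
best_first <- function(p) {
  order(-(p$n_adult + p$n_intact), -p$n_total, p$sample_id,
        method = "radix")
}

#' Run specimen-by-specimen identification over a schedule
#'
#' Processes the selected morphospecies in priority-rank order. For each,
#' pools are visited in [order_visits()] order; within a visit, up to
#' `per_visit_budget` adult specimens are drawn without replacement
#' (seeded, exchangeable within the pool) and each reveals its true
#' species from the pool's composition. After a visit the morphospecies'
#' sequence stops when the visit revealed no species new to that
#' morphospecies (`stop_no_new`), or when every new species appeared
#' exactly once in the visit (`stop_singletons`). Identification halts
#' globally once `capacity_budget` specimens have been prepared.
#'
#' The composition table is the latent truth in simulation mode
#' ([pool_composition()]) or a table of recorded outcomes in replay mode;
#' the machinery is identical.
#'
#' @param priority A `priority_table` with its `selected` column set.
#' @param pools Pools table; only adult specimens are identifiable, so at
#'   most `n_adult` specimens can be prepared from a pool.
#' @param metadata Sample metadata (see [order_visits()]).
#' @param composition Data frame `sample_id`, `morphospecies_id`,
#'   `species`, `count` giving each pool's species makeup.
#' @param per_visit_budget Specimens prepared per visit.
#' @param capacity_budget Global preparation capacity, or `Inf`.
#' @param stop_no_new,stop_singletons Logical switches for the two
#'   stop-rules.
#' @param seed Integer seed; each pool draws from its own substream so a
#'   larger budget extends, rather than reshuffles, the specimens drawn.
#' @param variables Stratifying variables for visit ordering.
#' @return List of class `identification_run`: `visits` (one row per
#'   visit), `revealed` (long table of species counts per visit), `taxa`
#'   (taxon list with prepared-specimen counts), `stream` (species of each
#'   prepared specimen in order) and `ledger`.
#' @export
run_identification <- function(priority, pools, metadata, composition,
                               per_visit_budget = 3L, capacity_budget = Inf,
                               stop_no_new = TRUE, stop_singletons = TRUE,
                               seed = 1L,
                               variables = c("region", "soil_type",
                                             "lui_class")) {
  stopifnot(inherits(priority, "priority_table"))
  if (per_visit_budget < 0 || capacity_budget < 0) stop("budget < 0")
  sel <- priority[priority$selected, , drop = FALSE]
  sel <- sel[order(sel$rank), , drop = FALSE]
  visits <- list()
  revealed <- list()
  stream <- character()
  prepared_total <- 0L
  for (m in sel$morphospecies_id) {
    if (prepared_total >= capacity_budget) break
    sched <- order_visits(m, pools, metadata, variables)
    seen <- character()
    for (k in seq_len(nrow(sched))) {
      if (prepared_total >= capacity_budget) break
      pool <- sched[k, ]
      comp <- composition[composition$sample_id == pool$sample_id &
                            composition$morphospecies_id == m, ,
                          drop = FALSE]
      specimens <- rep(comp$species, comp$count)
      # the pool's seeded permutation; its first n_adult specimens are the
      # adults, and preparation takes a prefix of those
      set.seed(stage_seed(seed, paste("ident", m, pool$sample_id)))
      specimens <- specimens[sample.int(length(specimens))]
      adults <- specimens[seq_len(min(pool$n_adult, length(specimens)))]
      n_prep <- min(per_visit_budget, length(adults),
                    capacity_budget - prepared_total)
      drawn <- adults[seq_len(n_prep)]
      prepared_total <- prepared_total + length(drawn)
      stream <- c(stream, drawn)
      tab <- table(drawn)
      new_species <- setdiff(names(tab), seen)
      seen <- union(seen, names(tab))
      visits[[length(visits) + 1L]] <- data.frame(
        morphospecies_id = m, sample_id = pool$sample_id, visit = k,
        n_prepared = length(drawn), n_new_species = length(new_species),
        stringsAsFactors = FALSE)
      if (length(tab) > 0L) {
        revealed[[length(revealed) + 1L]] <- data.frame(
          morphospecies_id = m, sample_id = pool$sample_id,
          species = names(tab), n = as.integer(tab),
          stringsAsFactors = FALSE)
      }
      if (stop_no_new && length(new_species) == 0L) break
      if (stop_singletons && length(new_species) > 0L &&
          all(tab[new_species] == 1L)) break
    }
  }
  visits <- if (length(visits) > 0L) do.call(rbind, visits) else
    data.frame(morphospecies_id = character(), sample_id = character(),
               visit = integer(), n_prepared = integer(),
               n_new_species = integer(), stringsAsFactors = FALSE)
  revealed <- if (length(revealed) > 0L) do.call(rbind, revealed) else
    data.frame(morphospecies_id = character(), sample_id = character(),
               species = character(), n = integer(),
               stringsAsFactors = FALSE)
  taxa <- if (nrow(revealed) > 0L) {
    agg <- aggregate(n ~ species, data = revealed, FUN = sum)
    data.frame(taxon = agg$species, taxon_rank = "species",
               count = as.integer(agg$n), stringsAsFactors = FALSE)
  } else {
    data.frame(taxon = character(), taxon_rank = character(),
               count = integer(), stringsAsFactors = FALSE)
  }
  taxa <- taxa[order(taxa$taxon), , drop = FALSE]
  rownames(taxa) <- NULL
  structure(
    list(visits = visits, revealed = revealed, taxa = taxa, stream = stream,
         ledger = effort_ledger(prepared = prepared_total)),
    class = "identification_run"
  )
}

#' Effort ledger
#'
#' Tracks the two components of identification effort: specimens prepared
#' for microscopy and specimens designated for sequencing.
#'
#' @param prepared Specimens prepared.
#' @param designated Specimens designated for sequencing.
#' @return List of class `effort_ledger` with `specimens_prepared`,
#'   `specimens_designated_for_sequencing` and their `total_effort`.
#' @export
effort_ledger <- function(prepared = 0L, designated = 0L) {
  stopifnot(prepared >= 0, designated >= 0)
  structure(
    list(specimens_prepared = as.integer(prepared),
         specimens_designated_for_sequencing = as.integer(designated),
         total_effort = as.integer(prepared + designated)),
    class = "effort_ledger"
  )
}

#' @export
print.effort_ledger <- function(x, ...) {
  cat(sprintf(
    "Effort ledger: %d prepared + %d designated for sequencing = %d total\n",
    x$specimens_prepared, x$specimens_designated_for_sequencing,
    x$total_effort))
  invisible(x)
}

#' @export
print.identification_run <- function(x, ...) {
  cat(sprintf(
    "Identification run: %d visits over %d morphospecies, %d taxa revealed\n",
    nrow(x$visits), length(unique(x$visits$morphospecies_id)),
    nrow(x$taxa)))
  print(x$ledger)
  invisible(x)
}
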