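# Benchmarking arithmetic: taxon-list overlap, effort ratio,
# abundance-weighted individual coverage, rank-abundance concentration and
# coverage-effort curves.

# canonical form for label comparison: trim, collapse whitespace,
# case-insensitive
normalise_label <- function(x) {
  tolower(gsub("[[:space:]]+", " ", trimws(x)))
}

genus_of <- function(x) {
  sub(" .*$", "", normalise_label(x))
}

as_taxon_labels <- function(x, what) {
  labels <- if (is.data.frame(x)) {
    if (!"taxon" %in% names(x)) stop(what, " has no taxon column")
    x$taxon
  } else {
    as.character(x)
  }
  if (anyDuplicated(normalise_label(labels))) {
    stop("duplicate taxon labels in ", what)
  }
  labels
}

#' Match two taxon lists
#'
#' In `exact_label` mode taxa match iff their normalised labels (trimmed,
#' whitespace-collapsed, case-insensitive) are equal, so a genus-level
#' record like `"Lepidocyrtus sp."` matches only the identical label and
#' never absorbs congeneric species. In `genus_rollup` mode taxa
#' additionally match when they share a genus.
#'
#' @param list_a,list_b Taxon lists: character vectors or data frames with
#'   a `taxon` column. Labels must be unique within each list.
#' @param mode `"exact_label"` (default) or `"genus_rollup"`.
#' @return List of class `taxon_match` with `overlap` (labels of `list_a`
#'   taxa that match), `a_only`, `b_only`, their counts and the mode.
#' @export
match_taxa <- function(list_a, list_b, mode = c("exact_label",
                                                "genus_rollup")) {
  mode <- match.arg(mode)
  a <- as_taxon_labels(list_a, "list_a")
  b <- as_taxon_labels(list_b, "list_b")
  na <- normalise_label(a)
  nb <- normalise_label(b)
  a_hit <- na %in% nb
  b_hit <- nb %in% na
  if (mode == "genus_rollup") {
    a_hit <- a_hit | genus_of(a) %in% genus_of(b)
    b_hit <- b_hit | genus_of(b) %in% genus_of(a)
  }
  structure(
    list(overlap = a[a_hit], a_only = a[!a_hit], b_only = b[!b_hit],
         overlap_count = sum(a_hit), a_only_count = sum(!a_hit),
         b_only_count = sum(!b_hit), mode = mode),
    class = "taxon_match"
  )
}

#' @export
print.taxon_match <- function(x, ...) {
  cat(sprintf("Taxon match (%s): %d shared, %d only in A, %d only in B\n",
              x$mode, x$overlap_count, x$a_only_count, x$b_only_count))
  invisible(x)
}

#' Ratio of identification efforts
#'
#' @param effort_a,effort_b Specimen counts (e.g., specimens given detailed
#'   identification under the stratified workflow vs. the exhaustive
#'   inventory).
#' @return `effort_a / effort_b`.
#' @export
effort_ratio <- function(effort_a, effort_b) {
  if (effort_b <= 0) stop("effort_b must be positive")
  if (effort_a < 0) stop("effort_a must be non-negative")
  effort_a / effort_b
}

#' Abundance-weighted individual coverage
#'
#' The fraction of benchmark individuals that belong to taxa present on a
#' detected taxon list: the sum of benchmark counts over taxa whose label
#' matches a detected taxon, divided by `denominator`.
#'
#' @param detected Character vector (or taxon data frame) of detected taxa.
#' @param benchmark Data frame with `taxon` and `count` columns.
#' @param denominator Total individuals to divide by; defaults to the sum
#'   of the benchmark counts. Must be at least the matched count sum.
#' @return Coverage in `[0, 1]`, with the matched individual count in the
#'   `matched_individuals` attribute.
#' @export
individual_coverage <- function(detected, benchmark, denominator = NULL) {
  stopifnot(is.data.frame(benchmark), all(c("taxon", "count") %in%
                                            names(benchmark)))
  if (any(benchmark$count < 0, na.rm = TRUE)) stop("negative benchmark count")
  det <- normalise_label(if (is.data.frame(detected)) detected$taxon else
    as.character(detected))
  hit <- normalise_label(benchmark$taxon) %in% det
  matched <- sum(benchmark$count[hit], na.rm = TRUE)
  if (is.null(denominator)) denominator <- sum(benchmark$count, na.rm = TRUE)
  if (denominator < matched) {
    stop("denominator smaller than the matched individual count")
  }
  if (denominator == 0) return(structure(0, matched_individuals = 0L))
  structure(matched / denominator, matched_individuals = as.integer(matched))
}

#' Share of individuals in the k most abundant taxa
#'
#' @param counts Named numeric vector of taxon counts (ties in abundance
#'   are broken by label).
#' @param k Number of top taxa.
#' @param total Denominator for the share; defaults to `sum(counts)`.
#' @return List with `sum` (individuals in the top `k`) and `share`.
#' @export
top_k_share <- function(counts, k, total = NULL) {
  stopifnot(k >= 0)
  if (is.null(total)) total <- sum(counts)
  if (k == 0L || length(counts) == 0L) {
    return(list(sum = 0, share = 0))
  }
  nm <- if (is.null(names(counts))) as.character(seq_along(counts)) else
    names(counts)
  ord <- order(-counts, nm, method = "radix")
  top <- sum(counts[ord][seq_len(min(k, length(counts)))])
  list(sum = top, share = if (total > 0) top / total else 0)
}

#' Coverage-effort curve of an identification stream
#'
#' After each prepared specimen, records the cumulative effort and the
#' cumulative abundance-weighted coverage of the taxa detected so far
#' against a benchmark list. Coverage is non-decreasing in effort.
#'
#' @param stream Character vector: the taxon revealed by each prepared
#'   specimen, in preparation order (e.g., the `stream` element of
#'   [run_identification()]).
#' @param benchmark Data frame with `taxon` and `count`.
#' @param denominator Coverage denominator (see [individual_coverage()]).
#' @return Data frame with `effort`, `taxon` and `coverage`.
#' @export
coverage_effort_curve <- function(stream, benchmark, denominator = NULL) {
  if (is.null(denominator)) denominator <- sum(benchmark$count, na.rm = TRUE)
  n <- length(stream)
  if (n == 0L) {
    return(data.frame(effort = integer(), taxon = character(),
                      coverage = numeric(), stringsAsFactors = FALSE))
  }
  bench_norm <- normalise_label(benchmark$taxon)
  cnt <- benchmark$count
  cnt[is.na(cnt)] <- 0
  first <- !duplicated(normalise_label(stream))
  gain <- numeric(n)
  idx <- match(normalise_label(stream), bench_norm)
  gain[first & !is.na(idx)] <- cnt[idx[first & !is.na(idx)]]
  data.frame(effort = seq_len(n), taxon = stream,
             coverage = cumsum(gain) / denominator,
             stringsAsFactors = FALSE)
}
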