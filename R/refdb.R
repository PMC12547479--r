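# Reference-database gap analysis: compare an identified taxon list with a
# catalogue of existing molecular references and turn the gaps into an
# ordered sequencing task list with voucher bookkeeping.

ref_rank <- c(none = 0L, barcode = 1L, genome = 2L)

#' Find reference-database gaps
#'
#' Creates a sequencing task for every taxon whose catalogue entry is
#' absent or whose data type ranks below the required one (the quality
#' ordering is none < barcode < genome). Genus-level taxa are matched by
#' exact label; with `genus_rollup = TRUE` a genus-level taxon is also
#' considered covered when any congeneric catalogue entry meets the
#' requirement. Tasks keep the order of the input taxon list (pass it
#' sorted by priority rank).
#'
#' @param taxa Taxon list: character vector or data frame with `taxon` and
#'   optionally `morphospecies_id`.
#' @param catalogue Data frame with `taxon`, `data_type` (`none`,
#'   `barcode`, `genome`) and optional `accession`.
#' @param required Required data type, `"genome"` or `"barcode"`.
#' @param genus_rollup Accept congeneric coverage for genus-level taxa.
#' @param n_specimens Specimens designated per task (>= 1).
#' @return Data frame of class `sequencing_tasks`: `taxon`,
#'   `morphospecies_id`, `n_specimens_designated`, `voucher_id`, `status`
#'   (all `"pending"`).
#' @export
gap_check <- function(taxa, catalogue, required = c("genome", "barcode"),
                      genus_rollup = FALSE, n_specimens = 1L) {
  required <- match.arg(required)
  stopifnot(n_specimens >= 1)
  labels <- as_taxon_labels(taxa, "taxon list")
  morph <- if (is.data.frame(taxa) && "morphospecies_id" %in% names(taxa)) {
    taxa$morphospecies_id
  } else {
    rep(NA_character_, length(labels))
  }
  if (anyDuplicated(normalise_label(catalogue$taxon))) {
    stop("duplicate taxa in catalogue")
  }
  bad <- setdiff(unique(catalogue$data_type), names(ref_rank))
  if (length(bad) > 0L) {
    stop("unknown data_type value(s): ", paste(bad, collapse = ", "))
  }
  cat_norm <- normalise_label(catalogue$taxon)
  level <- ref_rank[catalogue$data_type]
  have <- level[match(normalise_label(labels), cat_norm)]
  have[is.na(have)] <- 0L
  if (genus_rollup) {
    is_genus <- grepl("\\bsp\\b\\.?", normalise_label(labels))
    best_by_genus <- tapply(level, genus_of(catalogue$taxon), max)
    congeneric <- best_by_genus[genus_of(labels)]
    congeneric[is.na(congeneric)] <- 0L
    have <- ifelse(is_genus, pmax(have, congeneric), have)
  }
  gap <- have < ref_rank[required]
  n_gap <- sum(gap)
  out <- data.frame(
    taxon = labels[gap],
    morphospecies_id = morph[gap],
    n_specimens_designated = rep(as.integer(n_specimens), n_gap),
    voucher_id = rep(NA_character_, n_gap),
    status = rep("pending", n_gap),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "required") <- required
  attr(out, "n_covered") <- sum(!gap)
  class(out) <- c("sequencing_tasks", "data.frame")
  out
}

#' Record the outcome of a sequencing task
#'
#' Legal transitions go from `pending` to `sequenced` or `failed`. Marking
#' a task sequenced requires a voucher id unless explicitly waived (for
#' specimens whose body could not be recovered after DNA extraction).
#'
#' @param tasks A `sequencing_tasks` table.
#' @param taxon The taxon whose task is updated.
#' @param status New status, `"sequenced"` or `"failed"`.
#' @param voucher_id Voucher identifier of the deposited specimen.
#' @param waive_voucher Allow a sequenced task without a voucher.
#' @return The updated task table.
#' @export
record_outcome <- function(tasks, taxon, status, voucher_id = NULL,
                           waive_voucher = FALSE) {
  stopifnot(inherits(tasks, "sequencing_tasks"),
            status %in% c("pending", "sequenced", "failed"))
  i <- which(normalise_label(tasks$taxon) == normalise_label(taxon))
  if (length(i) != 1L) stop("no task for taxon: ", taxon)
  if (tasks$status[i] != "pending" || status == "pending") {
    stop(sprintf("illegal transition %s -> %s for '%s'", tasks$status[i],
                 status, taxon))
  }
  if (status == "sequenced" && is.null(voucher_id) && !waive_voucher) {
    stop("a sequenced task needs a voucher_id (or an explicit waiver)")
  }
  tasks$status[i] <- status
  if (!is.null(voucher_id)) tasks$voucher_id[i] <- voucher_id
  tasks
}

#' @export
print.sequencing_tasks <- function(x, ...) {
  cat(sprintf("Sequencing tasks (%s required): %d gaps, %d taxa covered\n",
              attr(x, "required"), nrow(x), attr(x, "n_covered")))
  print.data.frame(as.data.frame(x))
  invisible(x)
}
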