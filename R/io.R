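# Tab-separated, UTF-8, header mandatory, "." decimal point. Empty cells
# stay empty strings on disk (absence of a count is not a zero count) and
# become NA on read for typed columns.

#' Read a delimited table with schema validation
#'
#' Reads a tab-separated text file with a mandatory header row, checks that
#' required columns are present, and converts typed columns with
#' row-numbered parse errors. Unknown columns and row order are preserved.
#'
#' @param path Path to the file.
#' @param required Character vector of required column names.
#' @param integer_cols,numeric_cols Columns converted to integer/double;
#'   empty cells become `NA`, anything non-numeric is a parse error naming
#'   the row.
#' @param logical_cols Columns converted to logical; `yes/true/1` map to
#'   `TRUE`, empty cells and `no/false/0` to `FALSE`.
#' @return A `data.frame` with typed columns.
#' @export
read_table <- function(path, required = character(), integer_cols = character(),
                       numeric_cols = character(), logical_cols = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "", na.strings = NULL,
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (ncol(tab) == 0L) stop("no header row in ", path)
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in intersect(c(integer_cols, numeric_cols), names(tab))) {
    raw <- trimws(tab[[col]])
    raw[raw == ""] <- NA_character_
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(val))
    if (length(bad) > 0L) {
      stop(sprintf("cannot parse column '%s' as a number at row %d: '%s'",
                   col, bad[1L], raw[bad[1L]]))
    }
    tab[[col]] <- if (col %in% integer_cols) {
      if (any(!is.na(val) & val != floor(val))) {
        stop(sprintf("column '%s' must be integer-valued", col))
      }
      as.integer(val)
    } else {
      val
    }
  }
  for (col in intersect(logical_cols, names(tab))) {
    tab[[col]] <- tolower(trimws(tab[[col]])) %in% c("yes", "true", "1")
  }
  tab
}

#' Write a table as tab-separated text
#'
#' Logical columns are written as `yes`/empty so that blanks on disk mean
#' "absent", matching the conventions of the packaged fixtures; `NA` values
#' in typed columns are written as empty cells.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  out <- x
  for (col in names(out)) {
    if (is.logical(out[[col]])) out[[col]] <- ifelse(out[[col]], "yes", "")
    if (is.factor(out[[col]])) out[[col]] <- as.character(out[[col]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a plot metadata table
#'
#' Expects columns `plot_id`, `region`, `soil_type`, `lui` and optionally
#' the LUI components (`mowing`, `fertilisation`, `grazing`).
#'
#' @param path Path to `plots.tsv`.
#' @return Data frame of plot records.
#' @export
read_plots <- function(path) {
  tab <- read_table(path,
                    required = c("plot_id", "region", "soil_type", "lui"),
                    numeric_cols = c("lui", "mowing", "fertilisation",
                                     "grazing"))
  if (anyDuplicated(tab$plot_id)) stop("duplicate plot_id in ", path)
  if (any(!is.finite(tab$lui))) stop("non-finite lui in ", path)
  tab
}

#' Read a morphospecies-by-sample abundance matrix
#'
#' First column `sample_id`, remaining columns morphospecies with integer
#' counts.
#'
#' @param path Path to `morph_matrix.tsv`.
#' @return Integer matrix (samples x morphospecies) with sample ids as row
#'   names.
#' @export
read_morph_matrix <- function(path) {
  tab <- read_table(path, required = "sample_id")
  if (names(tab)[1L] != "sample_id") stop("first column must be sample_id")
  ids <- tab$sample_id
  if (anyDuplicated(ids)) stop("duplicate sample_id in ", path)
  counts <- tab[, -1L, drop = FALSE]
  for (col in names(counts)) {
    raw <- trimws(counts[[col]])
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val))
    if (length(bad) > 0L) {
      stop(sprintf("cannot parse count in column '%s' at row %d: '%s'",
                   col, bad[1L], raw[bad[1L]]))
    }
    counts[[col]] <- as.integer(val)
  }
  mat <- as.matrix(counts)
  rownames(mat) <- ids
  validate_morph_matrix(mat)
  mat
}

#' Write a morphospecies-by-sample matrix
#' @param mat Integer matrix with sample ids as row names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_morph_matrix <- function(mat, path) {
  df <- data.frame(sample_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_table(df, path)
}

validate_morph_matrix <- function(mat) {
  if (is.null(rownames(mat))) stop("morphospecies matrix needs sample ids")
  if (any(mat < 0)) stop("negative count in morphospecies matrix")
  invisible(mat)
}

#' Read a pools table
#'
#' One row per non-empty morphospecies pool in a sample, with total, adult
#' and intact specimen counts.
#'
#' @param path Path to `pools.tsv`.
#' @return Data frame with columns `sample_id`, `morphospecies_id`,
#'   `n_total`, `n_adult`, `n_intact`.
#' @export
read_pools <- function(path) {
  tab <- read_table(path,
                    required = c("sample_id", "morphospecies_id", "n_total",
                                 "n_adult", "n_intact"),
                    integer_cols = c("n_total", "n_adult", "n_intact"))
  if (any(tab$n_adult > tab$n_total) || any(tab$n_intact > tab$n_total)) {
    stop("pool adult/intact counts exceed totals in ", path)
  }
  tab
}

#' Read a taxon list
#' @param path Path to a `taxa.tsv`-style file with columns `taxon`,
#'   `taxon_rank` and optionally `count`.
#' @return Data frame.
#' @export
read_taxa <- function(path) {
  read_table(path, required = c("taxon", "taxon_rank"),
             integer_cols = "count")
}

#' Read a reference-database catalogue
#' @param path Path to `refdb.tsv` with columns `taxon`, `data_type`
#'   (`none`, `barcode` or `genome`) and optional `accession`.
#' @return Data frame.
#' @export
read_refdb <- function(path) {
  tab <- read_table(path, required = c("taxon", "data_type"))
  bad <- setdiff(unique(tab$data_type), c("none", "barcode", "genome"))
  if (length(bad) > 0L) {
    stop("unknown data_type value(s): ", paste(bad, collapse = ", "))
  }
  tab
}

#' Load the packaged benchmarking table fixture
#'
#' Returns the published comparison of a habitat-stratified workflow
#' inventory against an exhaustive benchmarking inventory of grassland
#' Collembola: one row per taxon with detection flags, morphospecies
#' assignment, specimen counts and genome-sequencing status for both
#' datasets. Blank cells in the printed table are `NA` counts (absence of a
#' count, never zero).
#'
#' The returned table carries the study's detailed-identification efforts
#' as attributes: `effort_strataseq` (345 specimens: 279 prepared for
#' microscopy plus 66 designated for genome sequencing) and
#' `effort_benchmark` (1539 specimens prepared for the exhaustive
#' inventory), of which `benchmark_identified` (1219) could be assigned to
#' species or genus level.
#'
#' @return Data frame of class `benchmark_table`.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1.tsv", package = "strataseq",
                      mustWork = TRUE)
  tab <- read_table(path,
                    required = c("order", "family", "taxon", "taxon_rank",
                                 "strataseq_detected", "morphospecies_id",
                                 "strataseq_count", "sequenced",
                                 "benchmark_detected", "benchmark_count"),
                    integer_cols = c("strataseq_count", "benchmark_count"),
                    logical_cols = c("strataseq_detected", "sequenced",
                                     "benchmark_detected"))
  if (anyDuplicated(tab$taxon)) stop("duplicate taxon labels in fixture")
  stopifnot(
    all(tab$benchmark_detected | is.na(tab$benchmark_count)),
    all(is.na(tab$benchmark_count) | tab$benchmark_count >= 1L),
    sum(tab$benchmark_count, na.rm = TRUE) == 1219L
  )
  attr(tab, "effort_strataseq") <- 345L
  attr(tab, "effort_benchmark") <- 1539L
  attr(tab, "benchmark_identified") <- 1219L
  class(tab) <- c("benchmark_table", "data.frame")
  tab
}

#' @export
print.benchmark_table <- function(x, ...) {
  cat(sprintf(
    "Benchmark table: %d taxa (%d workflow-detected, %d benchmark-detected, %d sequenced)\n",
    nrow(x), sum(x$strataseq_detected), sum(x$benchmark_detected),
    sum(x$sequenced)))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("... and", nrow(x) - 6L, "more rows\n")
  invisible(x)
}
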