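# Habitat-stratified subsetting: enumerate region-by-soil strata and pick
# one low- and one high-LUI plot per stratum from the outer LUI quartiles.

#' Compute a land-use intensity index
#'
#' LUI is the sum of the standardised values of the three primary
#' management components: mowing events per year, fertiliser amount, and
#' livestock units per hectare per year, each divided by its reference
#' mean.
#'
#' @param components Numeric vector of the three component values, or a
#'   matrix/data frame with one row per plot and three columns.
#' @param reference_means Positive numeric vector of the three reference
#'   means used for standardisation.
#' @return The LUI value(s): `sum(components / reference_means)` per plot.
#' @export
compute_lui <- function(components, reference_means = lui_reference_means) {
  if (any(!is.finite(reference_means)) || any(reference_means <= 0)) {
    stop("reference means must be positive")
  }
  if (is.data.frame(components)) components <- as.matrix(components)
  if (is.matrix(components)) {
    if (ncol(components) != length(reference_means)) {
      stop("components and reference_means disagree in length")
    }
    return(as.numeric(components %*% (1 / reference_means)))
  }
  if (length(components) != length(reference_means)) {
    stop("components and reference_means disagree in length")
  }
  sum(components / reference_means)
}

#' Enumerate habitat strata
#'
#' Strata are the distinct value tuples of the stratifying variables that
#' occur in the plot table; every plot belongs to exactly one stratum. The
#' result is ordered lexicographically by the variable values.
#'
#' @param plots Plot table with one row per plot.
#' @param variables Ordered character vector of stratifying columns.
#' @return Data frame with the stratifying columns, `stratum_id` and
#'   `n_plots`; the per-stratum plot ids are in the `members` attribute
#'   (a named list keyed by `stratum_id`).
#' @export
enumerate_strata <- function(plots, variables = c("region", "soil_type")) {
  missing_vars <- setdiff(variables, names(plots))
  if (length(missing_vars) > 0L) {
    stop("stratifying variable(s) not in plot table: ",
         paste(missing_vars, collapse = ", "))
  }
  if (nrow(plots) == 0L) {
    out <- plots[0L, variables, drop = FALSE]
    out$stratum_id <- character()
    out$n_plots <- integer()
    attr(out, "members") <- list()
    return(out)
  }
  key <- do.call(paste, c(plots[variables], sep = "|"))
  ord <- order(key, method = "radix")
  uk <- unique(key[ord])
  first <- match(uk, key)
  out <- plots[first, variables, drop = FALSE]
  rownames(out) <- NULL
  out$stratum_id <- uk
  out$n_plots <- as.integer(table(key)[uk])
  attr(out, "members") <- lapply(uk, function(k) plots$plot_id[key == k])
  names(attr(out, "members")) <- uk
  out
}

#' Select the habitat-stratified sample subset
#'
#' Per stratum, one plot is drawn uniformly at random from the lowest LUI
#' quartile and one from the highest. Quartiles are computed by linear
#' interpolation (quantile type 7) with inclusive bounds (`lui <= Q1`,
#' `lui >= Q3`), over the LUI values of the stratum itself
#' (`scope = "stratum"`, the default) or of the whole region
#' (`scope = "region"`). Strata with fewer than 4 plots fall back to the
#' minimum- and maximum-LUI plots; a single-plot stratum contributes that
#' plot once and is flagged degenerate. Changing the seed can change which
#' candidate is drawn but never the candidate sets.
#'
#' @param plots Plot table with `plot_id`, the stratifying columns and
#'   `lui`.
#' @param variables Ordered character vector of stratifying columns.
#' @param scope Quartile scope, `"stratum"` or `"region"`.
#' @param seed Integer seed for the per-stratum draws.
#' @return Data frame of class `subset_selection`: the stratifying columns,
#'   `low_plot_id`, `high_plot_id`, `q1`, `q3` and `degenerate`.
#' @export
select_subset <- function(plots, variables = c("region", "soil_type"),
                          scope = c("stratum", "region"), seed = 1L) {
  scope <- match.arg(scope)
  if (nrow(plots) == 0L) stop("plot table is empty")
  if (!"lui" %in% names(plots)) stop("plot table has no lui column")
  strata <- enumerate_strata(plots, variables)
  members <- attr(strata, "members")
  lui <- setNames(plots$lui, plots$plot_id)
  pick <- function(ids, rng_label) {
    set.seed(stage_seed(seed, rng_label))
    ids[sample.int(length(ids), 1L)]
  }
  res <- strata[, c(variables, "stratum_id"), drop = FALSE]
  res$low_plot_id <- NA_character_
  res$high_plot_id <- NA_character_
  res$q1 <- NA_real_
  res$q3 <- NA_real_
  res$degenerate <- FALSE
  for (i in seq_len(nrow(strata))) {
    ids <- members[[strata$stratum_id[i]]]
    v <- lui[ids]
    pool <- if (scope == "stratum") {
      v
    } else {
      lui[plots$plot_id[plots$region == strata$region[i]]]
    }
    q <- quantile(pool, c(0.25, 0.75), type = 7, names = FALSE)
    res$q1[i] <- q[1L]
    res$q3[i] <- q[2L]
    if (length(ids) == 1L) {
      res$low_plot_id[i] <- res$high_plot_id[i] <- ids
      res$degenerate[i] <- TRUE
      next
    }
    if (length(ids) < 4L) {
      lowc <- ids[v == min(v)]
      highc <- ids[v == max(v)]
    } else {
      lowc <- ids[v <= q[1L]]
      highc <- ids[v >= q[2L]]
      # with a region-wide quartile scope a stratum can miss a quartile;
      # fall back to its LUI extremes so every stratum stays represented
      if (length(lowc) == 0L) lowc <- ids[v == min(v)]
      if (length(highc) == 0L) highc <- ids[v == max(v)]
    }
    low <- pick(sort(lowc), paste0("subset-low:", strata$stratum_id[i]))
    high_pool <- setdiff(sort(highc), low)
    high <- if (length(high_pool) > 0L) {
      pick(high_pool, paste0("subset-high:", strata$stratum_id[i]))
    } else {
      low
    }
    if (lui[low] > lui[high]) { tmp <- low; low <- high; high <- tmp }
    res$low_plot_id[i] <- low
    res$high_plot_id[i] <- high
  }
  attr(res, "seed") <- as.integer(seed)
  attr(res, "scope") <- scope
  class(res) <- c("subset_selection", "data.frame")
  res
}

#' Samples selected by a subset selection
#'
#' @param selection A `subset_selection` from [select_subset()].
#' @return Character vector of the selected plot ids (a degenerate stratum
#'   contributes its single plot once).
#' @export
selected_samples <- function(selection) {
  stopifnot(inherits(selection, "subset_selection"))
  out <- character()
  for (i in seq_len(nrow(selection))) {
    out <- c(out, selection$low_plot_id[i])
    if (!identical(selection$high_plot_id[i], selection$low_plot_id[i])) {
      out <- c(out, selection$high_plot_id[i])
    }
  }
  out
}

#' @export
print.subset_selection <- function(x, ...) {
  cat(sprintf(
    "Habitat-stratified subset: %d strata (%d degenerate), %d samples, LUI quartiles per %s\n",
    nrow(x), sum(x$degenerate), length(selected_samples(x)),
    attr(x, "scope")))
  print.data.frame(as.data.frame(x))
  invisible(x)
}

#' Recode LUI into high/low classes
#'
#' Plots above the mean LUI of the supplied table are `"high"`, the rest
#' `"low"`; used as the third stratifying variable when scoring habitat
#' distinctness between samples.
#'
#' @param lui Numeric vector of LUI values.
#' @return Character vector of `"high"`/`"low"`.
#' @export
lui_class <- function(lui) {
  if (any(!is.finite(lui))) stop("non-finite lui")
  ifelse(lui > mean(lui), "high", "low")
}
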