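# Community statistics used around the workflow: Bray-Curtis
# dissimilarity, PERMANOVA with sequential sums of squares, non-metric
# multidimensional scaling, and the sequential-ANOVA richness model.
# Counts enter untransformed: sampling effort was comparable across sites,
# so abundance differences are treated as signal, not artefact.

#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum |x_i - y_i| / sum (x_i + y_i)` on raw count vectors,
#' bounded in `[0, 1]`. The distance between two all-empty samples is
#' undefined, so two or more all-zero rows are an error naming the
#' samples.
#'
#' @param mat Samples x taxa count matrix (non-negative).
#' @return A `dist` object.
#' @export
bray_curtis <- function(mat) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("negative counts")
  zero <- rowSums(mat) == 0
  if (sum(zero) >= 2L) {
    nm <- rownames(mat)[zero]
    if (is.null(nm)) nm <- which(zero)
    stop("distance undefined between all-zero samples: ",
         paste(nm, collapse = ", "))
  }
  vegan::vegdist(mat, method = "bray")
}

#' PERMANOVA with sequential sums of squares
#'
#' Partitions the (Gower-centred) sum of squares of a distance matrix
#' among model terms added sequentially in the given order, with pseudo-F
#' statistics and permutation p-values computed by freely permuting sample
#' labels (`p = (1 + #{F* >= F}) / (1 + n_perm)`). Because the sums of
#' squares are sequential, the per-term R-squared values depend on the
#' term order.
#'
#' @param d A `dist` object or symmetric distance matrix.
#' @param metadata Data frame of sample covariates, rows in the order of
#'   `d`.
#' @param terms Ordered character vector of metadata columns.
#' @param n_perm Number of permutations (>= 1; default 999).
#' @param seed Integer seed for the permutation stream.
#' @return Data frame of class `permanova_table` with one row per term
#'   plus `Residual` and `Total`: `term`, `df`, `ss`, `r2`, `f`, `p`.
#' @export
permanova <- function(d, metadata, terms, n_perm = 999L, seed = 1L) {
  d <- as.dist(d)
  n <- attr(d, "Size")
  stopifnot(nrow(metadata) == n, n_perm >= 1)
  missing_terms <- setdiff(terms, names(metadata))
  if (length(missing_terms) > 0L) {
    stop("term(s) not in metadata: ", paste(missing_terms, collapse = ", "))
  }
  if (sum(d^2) / n < 1e-12) {
    stop("total sum of squares is zero: all samples are identical")
  }
  df <- metadata[, terms, drop = FALSE]
  for (tm in terms) {
    v <- df[[tm]]
    if (is.character(v)) v <- df[[tm]] <- factor(v)
    if (is.factor(v) && nlevels(droplevels(v)) < 2L) {
      stop("term '", tm, "' is constant (0 degrees of freedom)")
    }
    if (is.numeric(v) && var(v) == 0) {
      stop("term '", tm, "' is constant (0 degrees of freedom)")
    }
  }
  set.seed(seed)
  fit <- vegan::adonis2(d ~ ., data = df, permutations = n_perm,
                        by = "terms")
  out <- data.frame(
    term = rownames(fit),
    df = fit$Df,
    ss = fit$SumOfSqs,
    r2 = fit$R2,
    f = fit$F,
    p = fit[["Pr(>F)"]],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_perm") <- as.integer(n_perm)
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("permanova_table", "data.frame")
  validate_permanova_table(out)
  out
}

# typed invariants of a PERMANOVA table, checked on every run
validate_permanova_table <- function(x) {
  tot <- x$ss[x$term == "Total"]
  parts <- x$ss[x$term != "Total"]
  if (abs(sum(parts) - tot) > 1e-9 * max(1, abs(tot))) {
    stop("sums of squares do not add up to the total")
  }
  r2 <- x$r2[x$term != "Total"]
  if (abs(sum(r2) - 1) > 1e-9) stop("R-squared values do not sum to 1")
  p <- x$p[!is.na(x$p)]
  np <- attr(x, "n_perm")
  if (any(p < 1 / (np + 1) - 1e-12) || any(p > 1 + 1e-12)) {
    stop("permutation p-value out of range")
  }
  invisible(x)
}

#' @export
print.permanova_table <- function(x, ...) {
  cat(sprintf("PERMANOVA (sequential SS, %d permutations)\n",
              attr(x, "n_perm")))
  print.data.frame(as.data.frame(x), digits = 4L)
  invisible(x)
}

#' Non-metric multidimensional scaling
#'
#' Embeds a dissimilarity matrix in `k` dimensions by minimising Kruskal
#' stress-1 against the monotone (isotonic) regression of configuration
#' distances on the ranked input dissimilarities, using several seeded
#' random starts plus a metric-scaling start and keeping the best
#' solution.
#'
#' @param d A `dist` object or symmetric distance matrix.
#' @param k Embedding dimension (`1 <= k < n`).
#' @param restarts Number of random restarts.
#' @param max_iter Maximum iterations per start.
#' @param seed Integer seed.
#' @return List of class `nmds_result` with `points` (n x k), `stress`,
#'   `restarts` and `seed`. Stress is invariant to rotation, reflection
#'   and translation of the configuration.
#' @export
nmds <- function(d, k = 2L, restarts = 20L, max_iter = 200L, seed = 1L) {
  d <- as.dist(d)
  n <- attr(d, "Size")
  if (k >= n) stop("k must be smaller than the number of samples")
  if (k < 1) stop("k must be at least 1")
  set.seed(seed)
  sol <- suppressWarnings(suppressMessages(
    vegan::metaMDS(d, k = k, trymax = restarts, maxit = max_iter,
                   trace = 0, autotransform = FALSE, wascores = FALSE)
  ))
  structure(
    list(points = sol$points, stress = sol$stress,
         restarts = as.integer(restarts), seed = as.integer(seed),
         converged = isTRUE(sol$converged > 0)),
    class = "nmds_result"
  )
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("NMDS: %d samples in %d dimensions, stress %.4f\n",
              nrow(x$points), ncol(x$points), x$stress))
  invisible(x)
}

#' Richness linear model with sequential sums of squares
#'
#' Ordinary least squares of per-sample richness on the model terms, with
#' Type I (sequential) sums of squares in the given order and per-term F
#' tests. A constant response yields zero F for every term.
#'
#' @param richness Numeric vector of per-sample richness.
#' @param metadata Data frame of sample covariates.
#' @param terms Ordered character vector of metadata columns.
#' @return Data frame with one row per term plus `Residuals`: `term`,
#'   `df`, `ss`, `f`, `p`.
#' @export
richness_anova <- function(richness, metadata, terms) {
  stopifnot(length(richness) == nrow(metadata))
  missing_terms <- setdiff(terms, names(metadata))
  if (length(missing_terms) > 0L) {
    stop("term(s) not in metadata: ", paste(missing_terms, collapse = ", "))
  }
  dat <- cbind(data.frame(richness = richness), metadata[, terms,
                                                         drop = FALSE])
  fit <- lm(reformulate(terms, response = "richness"), data = dat)
  if (stats::df.residual(fit) < 1L) stop("saturated model: no residual df")
  constant <- var(richness) == 0
  a <- if (constant) suppressWarnings(anova(fit)) else anova(fit)
  out <- data.frame(
    term = rownames(a),
    df = a$Df,
    ss = a$`Sum Sq`,
    f = a$`F value`,
    p = a$`Pr(>F)`,
    stringsAsFactors = FALSE
  )
  if (constant) {
    out$f[out$term != "Residuals"] <- 0
    out$p[out$term != "Residuals"] <- 1
  }
  rownames(out) <- NULL
  out
}
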