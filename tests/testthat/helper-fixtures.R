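# Small in-code fixtures shared across tests.

# A plot table with the study's stratum structure: 3 regions with 2, 3 and
# 6 region-specific soil types, n plots per stratum with distinct LUI
# values spread over the stratum.
study_structure_plots <- function(n_per_stratum = 8L) {
  soils <- c(2L, 3L, 6L)
  rows <- list()
  for (r in 1:3) {
    for (s in seq_len(soils[r])) {
      rows[[length(rows) + 1L]] <- data.frame(
        region = paste0("R", r),
        soil_type = sprintf("R%d_soil%d", r, s),
        lui = seq(0.5, 3.5, length.out = n_per_stratum) +
          (r * 10L + s) * 1e-4,  # distinct values across strata
        stringsAsFactors = FALSE)
    }
  }
  plots <- do.call(rbind, rows)
  plots$plot_id <- sprintf("P%03d", seq_len(nrow(plots)))
  plots[, c("plot_id", "region", "soil_type", "lui")]
}

# tiny morphospecies matrix with known occupancy/abundance structure
toy_morph_matrix <- function() {
  m <- matrix(c(2L, 0L, 1L,
                0L, 0L, 1L,
                5L, 0L, 1L), nrow = 3L, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"), c("m1", "m2", "m3")))
  m
}

# metadata for three samples with known pairwise habitat distances:
# d(s1,s2) = 3, d(s1,s3) = 1, d(s2,s3) = 2
toy_schedule_metadata <- function() {
  data.frame(
    plot_id = c("s1", "s2", "s3"),
    region = c("R1", "R2", "R1"),
    soil_type = c("a", "b", "a"),
    lui_class = c("low", "high", "high"),
    stringsAsFactors = FALSE)
}

# independent maximin-ordering oracle: enumerate all visit orders starting
# from `first` and keep those that are farthest-point-greedy at each step
maximin_orders <- function(d, first) {
  n <- nrow(d)
  orders <- list(first)
  for (step in seq_len(n - 1L)) {
    nxt <- list()
    for (o in orders) {
      rem <- setdiff(seq_len(n), o)
      mind <- vapply(rem, function(i) min(d[i, o]), numeric(1L))
      for (i in rem[mind == max(mind)]) nxt[[length(nxt) + 1L]] <- c(o, i)
    }
    orders <- nxt
  }
  orders
}

# Kruskal stress-1 of a fixed 1-D configuration against dissimilarities dv
stress1_config <- function(xs, dv) {
  conf <- as.vector(dist(xs))
  o <- order(dv)
  fit <- stats::isoreg(dv[o], conf[o])$yf
  sqrt(sum((conf[o] - fit)^2) / sum(conf^2))
}
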