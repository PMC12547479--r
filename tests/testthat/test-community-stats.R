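test_that("Bray-Curtis reproduces its closed forms", {
  m <- rbind(a = c(1, 1, 0), b = c(1, 1, 0), c = c(0, 0, 3))
  d <- as.matrix(bray_curtis(m))
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 1)          # disjoint supports
  m2 <- rbind(x = c(1, 1, 0), y = c(0, 1, 1))
  expect_equal(as.numeric(bray_curtis(m2)), 0.5)

  # invariant to appending all-zero taxon columns
  expect_equal(as.numeric(bray_curtis(cbind(m, 0, 0))),
               as.numeric(bray_curtis(m)))
  expect_error(bray_curtis(rbind(a = c(0, 0), b = c(0, 0), c = c(1, 0))),
               "all-zero.*a.*b")
  expect_error(bray_curtis(m - 2), "negative")
})

test_that("PERMANOVA pseudo-F equals classical ANOVA F on Euclidean data", {
  set.seed(10)
  for (rep in 1:3) {
    x <- rnorm(14)
    g <- factor(sample(rep(c("a", "b"), 7)))
    pt <- permanova(dist(x), data.frame(g = g), "g", n_perm = 99, seed = rep)
    f_aov <- summary(stats::aov(x ~ g))[[1L]][["F value"]][1L]
    expect_equal(pt$f[pt$term == "g"], f_aov, tolerance = 1e-9)
  }
})

test_that("PERMANOVA tables satisfy their typed invariants on random inputs", {
  set.seed(21)
  for (rep in 1:4) {
    mat <- matrix(rpois(15L * 6L, 4), nrow = 15L,
                  dimnames = list(paste0("s", 1:15), NULL))
    meta <- data.frame(g = sample(c("u", "v", "w"), 15L, replace = TRUE),
                       z = rnorm(15L))
    pt <- permanova(bray_curtis(mat), meta, c("g", "z"), n_perm = 49,
                    seed = rep)
    terms <- pt$term[!pt$term %in% c("Residual", "Total")]
    expect_setequal(terms, c("g", "z"))
    expect_equal(sum(pt$ss[pt$term != "Total"]),
                 pt$ss[pt$term == "Total"], tolerance = 1e-9)
    expect_equal(sum(pt$r2[pt$term != "Total"]), 1, tolerance = 1e-9)
    p <- pt$p[!is.na(pt$p)]
    expect_true(all(p >= 1 / 50 & p <= 1))
  }
})

test_that("degenerate PERMANOVA inputs raise explicit errors", {
  meta <- data.frame(g = rep(c("a", "b"), 3L), k = "const")
  ident <- matrix(1, 6L, 3L)  # all samples identical -> zero total SS
  expect_error(permanova(dist(ident), meta, "g", n_perm = 9),
               "sum of squares is zero")
  mat <- matrix(rpois(18, 4), 6L)
  expect_error(permanova(bray_curtis(mat), meta, "k", n_perm = 9),
               "constant")
  expect_error(permanova(bray_curtis(mat), meta, "missing", n_perm = 9),
               "missing")
})

test_that("NMDS recovers exact embeddings and is permutation-invariant", {
  set.seed(4)
  pts <- matrix(rnorm(20L), 10L, 2L)
  d <- dist(pts)
  r <- nmds(d, k = 2L, restarts = 5L, seed = 1L)
  expect_lt(r$stress, 1e-3)

  perm <- sample(10L)
  d_perm <- as.dist(as.matrix(d)[perm, perm])
  r_perm <- nmds(d_perm, k = 2L, restarts = 5L, seed = 1L)
  expect_equal(r_perm$stress, r$stress, tolerance = 1e-6)
  expect_error(nmds(d, k = 10L), "smaller")
})

test_that("1-D NMDS stress agrees with an exhaustive grid-search oracle", {
  # four generic planar points (tie-free dissimilarities, so the isotonic
  # fit has a unique ordering and no degenerate zero-stress solutions)
  pts <- matrix(c(0, 0, 1, 0.25, 0.3, 1.1, 1.4, 1.6), 4L, 2L, byrow = TRUE)
  d <- dist(pts)
  r <- nmds(d, k = 1L, restarts = 30L, seed = 2L)
  dv <- as.vector(d)
  best <- Inf
  for (x3 in seq(-2, 5, by = 0.04)) {
    for (x4 in seq(-2, 6, by = 0.04)) {
      best <- min(best, stress1_config(c(0, 1, x3, x4), dv))
    }
  }
  expect_lt(abs(r$stress - best), 1e-2)
})

test_that("best-of-restarts stress never increases with dimension", {
  set.seed(6)
  mat <- matrix(rpois(12L * 8L, 3), 12L)
  d <- bray_curtis(mat)
  stresses <- vapply(1:3, function(k) {
    nmds(d, k = k, restarts = 10L, seed = 3L)$stress
  }, numeric(1L))
  expect_true(all(diff(stresses) <= 1e-6))
})

test_that("richness ANOVA uses sequential sums of squares", {
  set.seed(8)
  meta <- data.frame(g = factor(rep(c("a", "b"), each = 6L)),
                     z = rnorm(12L))
  rich <- rpois(12L, 8)
  a <- richness_anova(rich, meta, c("g", "z"))
  expect_identical(a$term, c("g", "z", "Residuals"))
  expect_identical(a$df[1L], 1L)

  # single 2-level factor: F equals the squared equal-variance t statistic
  t_stat <- stats::t.test(rich ~ meta$g, var.equal = TRUE)$statistic
  a1 <- richness_anova(rich, meta, "g")
  expect_equal(a1$f[1L], unname(t_stat^2), tolerance = 1e-9)

  # constant response: zero F everywhere
  a0 <- richness_anova(rep(5, 12L), meta, c("g", "z"))
  expect_true(all(a0$f[a0$term != "Residuals"] == 0))
  expect_error(richness_anova(rich[c(1, 7, 8)], meta[c(1, 7, 8), ],
                              c("g", "z")),
               "saturated")
})
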