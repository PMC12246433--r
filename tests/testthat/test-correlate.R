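named <- function(x, prefix = "m") stats::setNames(x, sprintf("%s%02d", prefix, seq_along(x)))

test_that("spearman correlation handles monotone, reversed and hand-computed cases", {
  x <- named(c(1, 2, 3, 4))
  expect_equal(spearman_cor(x, 2 * x)$rho, 1)
  expect_equal(spearman_cor(x, named(c(4, 3, 2, 1)))$rho, -1)
  # ranks equal values; Pearson on ranks: covariance 4, variances 5 -> 0.8
  expect_equal(spearman_cor(x, named(c(1, 3, 2, 4)))$rho, 0.8, tolerance = 1e-12)

  expect_error(spearman_cor(named(c(1, 2)), named(c(1, 2))), "3 paired")
  const <- spearman_cor(named(c(1, 1, 1, 2)), named(c(1, 1, 1, 1)),
                        policy = "union")
  expect_true(is.na(const$rho))
})

test_that("spearman is invariant under strictly increasing transforms", {
  set.seed(31)
  for (i in 1:20) {
    x <- named(stats::runif(8, 0.1, 1))
    y <- named(stats::runif(8, 0.1, 1))
    base <- spearman_cor(x, y)$rho
    expect_equal(spearman_cor(named(exp(3 * x)), y)$rho, base, tolerance = 1e-12)
    expect_equal(spearman_cor(x, named(y^3))$rho, base, tolerance = 1e-12)
  }
})

test_that("union policy zero-fills non-overlapping supports; intersection drops them", {
  x <- stats::setNames(c(0.4, 0.3, 0.2, 0.1, 0), sprintf("m%d", 1:5))
  y <- stats::setNames(c(0, 0.2, 0.3, 0.4, 0.1), sprintf("m%d", 1:5))
  u <- spearman_cor(x, y, policy = "union")
  i <- spearman_cor(x, y, policy = "intersection")
  expect_identical(u$n, 5L)
  expect_identical(i$n, 3L)
  expect_equal(u$rho, rho_brute(x, y), tolerance = 1e-12)
})

test_that("rho matches the rank-then-Pearson brute force on random vectors", {
  set.seed(77)
  for (i in 1:60) {
    n <- sample(4:12, 1)
    x <- named(stats::runif(n, 0.01, 1))
    y <- if (i %% 3 == 0) {
      named(sample(seq(0.1, 0.5, 0.1), n, replace = TRUE))  # ties
    } else {
      named(stats::runif(n, 0.01, 1))
    }
    if (stats::sd(rank(y)) == 0) next
    expect_equal(spearman_cor(x, y)$rho, rho_brute(x, y), tolerance = 1e-12)
  }
})

test_that("correlation matrices are symmetric with unit diagonal", {
  set.seed(5)
  profiles <- lapply(1:3, function(i) named(stats::runif(10, 0.01, 1)))
  names(profiles) <- c("s1", "s2", "s3")
  cm <- correlation_matrix(profiles)
  expect_equal(diag(cm$rho), c(s1 = 1, s2 = 1, s3 = 1))
  expect_equal(cm$rho, t(cm$rho), tolerance = 1e-12)
  expect_identical(sum(upper.tri(cm$rho)), 3L)   # n(n-1)/2 unique pairs

  twin <- correlation_matrix(list(a = profiles[[1]], b = profiles[[1]]))
  expect_equal(twin$rho["a", "b"], 1)
})

test_that("block statistics summarise unique pairs with population SDs", {
  rho <- matrix(0.5, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  diag(rho) <- 1
  cm <- structure(list(rho = rho, p = rho * NA, policy = "union"),
                  class = "cor_block_summary")
  one <- block_stats(cm, stats::setNames(rep("g", 3), c("x", "y", "z")))
  expect_equal(one$blocks$mean_rho, 0.5)
  expect_equal(one$blocks$sd_rho, 0)
  expect_identical(one$blocks$n_pairs, 3L)

  two <- block_stats(cm, stats::setNames(c("a", "b", "b"), c("x", "y", "z")),
                     block_pairs = list(c("a", "b")))
  expect_identical(two$blocks$n_pairs, 2L)

  single <- block_stats(cm, stats::setNames(c("a", "b", "c"), c("x", "y", "z")),
                        block_pairs = list(c("a", "b")))
  expect_identical(single$blocks$n_pairs, 1L)
  expect_equal(single$blocks$sd_rho, 0)

  expect_error(block_stats(cm, stats::setNames(c("a", "a", "b"), c("x", "y", "z")),
                           block_pairs = list(c("b", "b"))), "empty")
  expect_error(block_stats(cm, stats::setNames(c("a", "b"), c("x", "y"))), "cover")
})

test_that("group comparisons match closed forms and the exact Mann-Whitney enumeration", {
  same <- compare_coefficient_groups(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3), "student_t")
  expect_equal(same$p_value, 1)
  expect_identical(same$direction, "a=b")

  sep <- compare_coefficient_groups(c(0.1, 0.2), c(0.8, 0.9), "welch_t")
  expect_lt(sep$p_value, 0.05)
  expect_identical(sep$direction, "a<b")

  set.seed(13)
  sizes <- list(c(3, 3), c(2, 6), c(4, 5), c(6, 6))
  for (sz in sizes) {
    a <- stats::runif(sz[1])
    b <- stats::runif(sz[2])
    got <- compare_coefficient_groups(a, b, "mann_whitney")$p_value
    expect_equal(got, mann_whitney_brute(a, b), tolerance = 1e-12)
  }
})

test_that("PCA reproduces degenerate geometries and decomposes the variance", {
  set.seed(21)
  base <- matrix(stats::runif(30, 0.01, 1), nrow = 10,
                 dimnames = list(sprintf("m%d", 1:10), c("s1", "s2", "s3")))
  fr <- normalize_total(probe_matrix(base))
  dup <- cbind(unclass(fr), s3_copy = fr[, "s3"])
  pc <- pca_profiles(structure(dup, class = c("fraction_matrix", "matrix", "array")))
  expect_equal(pc$scores["s3", ], pc$scores["s3_copy", ], tolerance = 1e-9)
  expect_equal(sum(pc$var_explained), 1, tolerance = 1e-9)
  expect_true(all(diff(pc$var_explained) <= 1e-12))

  # two samples always lie on a line: PC1 carries all variance
  two <- pca_profiles(fr[, 1:2])
  expect_equal(two$var_explained[1], 1, tolerance = 1e-9)
  # collinear triple
  line <- cbind(s1 = base[, 1], s2 = base[, 1] + 1, s3 = base[, 1] + 2)
  pc_line <- pca_profiles(structure(line, class = c("fraction_matrix", "matrix", "array")))
  expect_equal(pc_line$var_explained[1], 1, tolerance = 1e-9)
})
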