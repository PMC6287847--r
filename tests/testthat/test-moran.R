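test_that("global Moran's I matches first principles and the brute-force oracle", {
  # two mutually-neighbouring areas: z1 = -z2 forces I = -1
  w2 <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(global_moran(c(3, 7), w2), -1)

  # 3x3 rook grid with x = 1..9 against the double-sum oracle
  w <- rook_grid_weights(3, 3)
  expect_equal(global_moran(1:9, w), moran_bruteforce(1:9, w$w),
               tolerance = 1e-12)

  # invariance: location shift, positive scale, simultaneous relabelling
  x <- c(2, 5, 1, 9, 4, 4, 7, 0, 3)
  expect_equal(global_moran(x + 100, w), global_moran(x, w))
  expect_equal(global_moran(2.5 * x, w), global_moran(x, w))
  set.seed(3)
  p <- sample(9)
  expect_equal(global_moran(x[p], w$w[p, p]), global_moran(x, w))

  expect_error(global_moran(rep(1, 9), w), "constant")
})

test_that("local Moran's I decomposes the global statistic", {
  w <- rook_grid_weights(4, 4)
  set.seed(21)
  x <- rnorm(16)
  li <- local_moran(x, w)
  expect_equal(unname(li), local_moran_bruteforce(x, w$w), tolerance = 1e-12)
  # sum_i I_i = S0 * I
  expect_equal(sum(li), sum(w$w) * global_moran(x, w), tolerance = 1e-10)
  # scale invariance
  expect_equal(local_moran(2 * x, w), li)

  # isolated area (all-zero weight row) contributes exactly 0
  m <- w$w
  m[2, ] <- 0; m[, 2] <- 0
  expect_equal(unname(local_moran(x, m)[2]), 0)
})

test_that("permutation inference is deterministic, bounded below, and honest", {
  w <- rook_grid_weights(4, 4)
  set.seed(5)
  x <- rnorm(16)
  a <- moran_mc_test(x, w, nperm = 99, seed = 42)
  b <- moran_mc_test(x, w, nperm = 99, seed = 42)
  expect_identical(a$p_value, b$p_value)
  expect_identical(a$sim, b$sim)
  expect_equal(a$expectation, -1 / 15)
  expect_gte(a$p_value, 1 / 100)

  # a strong smooth gradient attains the minimum pseudo p of 1/(nperm + 1)
  g <- make_grid_lattice(6, 6)
  grad <- g$centroids[, 1] + g$centroids[, 2]
  res <- moran_mc_test(grad + rnorm(36, 0, 0.1), lattice_weights(g),
                       nperm = 999, seed = 1)
  expect_equal(res$p_value, 1 / 1000)

  expect_error(moran_mc_test(rep(2, 16), w, seed = 1), "constant")
  expect_error(moran_mc_test(x, w, nperm = 5), "at least 19")
})

test_that("two-sided permutation inference detects negative autocorrelation", {
  g <- make_grid_lattice(6, 6)
  chk <- (-1)^(floor(g$centroids[, 1]) + floor(g$centroids[, 2]))
  w <- lattice_weights(g)
  res <- moran_mc_test(chk + rnorm(36, 0, 0.05), w, nperm = 499,
                       alternative = "two-sided", seed = 9)
  expect_lt(res$statistic, 0)
  expect_equal(res$p_value, 1 / 500)
})

test_that("LISA classification labels clusters and outliers correctly", {
  # perfect checkerboard: interior significant areas are HL/LH, never HH/LL
  g <- make_grid_lattice(8, 8)
  w <- lattice_weights(g)
  chk <- (-1)^(g$centroids[, 1] + g$centroids[, 2])
  set.seed(2)
  x <- chk + rnorm(64, 0, 0.05)
  res <- lisa_classify(x, w, nperm = 999, alpha = 0.05, bonferroni = FALSE,
                       seed = 4)
  sig <- res$cluster != "NS"
  expect_gt(sum(sig), 0)
  expect_true(all(res$cluster[sig] %in% c("HL", "LH")))

  # a smooth gradient produces HH and LL clusters at the extremes
  grad <- g$centroids[, 1] + g$centroids[, 2] + rnorm(64, 0, 0.3)
  res2 <- lisa_classify(grad, w, nperm = 999, alpha = 0.05,
                        bonferroni = FALSE, seed = 4)
  expect_true(all(res2$cluster[res2$cluster != "NS"] %in% c("HH", "LL")))

  # alpha = 0: nothing is significant
  res0 <- lisa_classify(x, w, nperm = 99, alpha = 0, seed = 4)
  expect_true(all(res0$cluster == "NS"))
})

test_that("Bonferroni correction divides the threshold by the area count", {
  g <- make_grid_lattice(4, 4)
  w <- lattice_weights(g)
  set.seed(8)
  x <- rnorm(16)
  res <- lisa_classify(x, w, nperm = 99, alpha = 0.05, bonferroni = TRUE,
                       seed = 1)
  expect_equal(attr(res, "threshold"), 0.05 / 16)
  expect_equal(res$p_adjusted, pmin(1, res$p_value * 16))
  # at the study scale of 141 areas the per-area level is 0.05/141
  expect_equal(0.05 / 141, 3.546e-4, tolerance = 1e-3)

  off <- lisa_classify(x, w, nperm = 99, alpha = 0.05, bonferroni = FALSE,
                       seed = 1)
  expect_equal(off$p_adjusted, off$p_value)
})
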