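test_that("simulated populations and covariates match the design targets", {
  lat <- make_grid_lattice(12, 12)
  out <- simulate_population_and_covariates(lat, seed = 101)

  totals <- tapply(out$population$population, out$population$area_id, sum)
  expect_equal(length(totals), 144)
  expect_true(all(out$population$population >= 0))
  # mean area total within 10% of the configured 12,901
  expect_lt(abs(mean(totals) / 12901 - 1), 0.10)

  # rurality: ordinal 1..6, level 1 most frequent, median at most 2, full span
  r <- out$covariates$rurality
  expect_setequal(sort(unique(r)), 1:6)
  expect_lte(median(r), 2)
  expect_equal(which.max(tabulate(r)), 1L)

  # continuous covariates confined to their configured ranges
  expect_true(all(out$covariates$no2 >= 3.64 & out$covariates$no2 <= 24.84))
  expect_true(all(out$covariates$deprivation >= -1.15 &
                  out$covariates$deprivation <= 1.46))
  expect_true(all(out$covariates$rh >= 56.02 & out$covariates$rh <= 69.56))

  # bit-reproducible under a fixed seed
  out2 <- simulate_population_and_covariates(lat, seed = 101)
  expect_identical(out, out2)

  bad <- study_config()
  bad$strata <- character(0)
  expect_error(simulate_population_and_covariates(lat, bad, seed = 1),
               "non-empty")
})

test_that("Leroux effects reduce to iid normals at rho = 0", {
  # disconnected lattice: all-zero weights
  w0 <- spatial_weights(matrix(0, 4, 4))
  draws <- sample_leroux_effects(w0, rho = 0, tau2 = 1, seed = 5,
                                 ndraws = 10000)
  v <- apply(draws, 1, var)
  expect_true(all(v > 0.94 & v < 1.06))
  # independence: pairwise sample correlations below 3/sqrt(ndraws)
  cm <- cor(t(draws))
  expect_lt(max(abs(cm[upper.tri(cm)])), 3 / sqrt(10000))
  # normality of a margin
  expect_gt(shapiro.test(draws[1, 1:5000])$p.value, 0.001)
})

test_that("Leroux effects on a connected pair match the dense-inverse oracle", {
  w <- spatial_weights(matrix(c(0, 1, 1, 0), 2, 2))
  draws <- sample_leroux_effects(w, rho = 0.5, tau2 = 1, seed = 77,
                                 ndraws = 50000)
  emp <- cov(t(draws))
  q <- matrix(c(1, -0.5, -0.5, 1), 2, 2)  # rho*d + 1 - rho on the diagonal
  expect_lt(max(abs(emp - solve(q))), 0.02)

  # determinism contract
  a <- sample_leroux_effects(w, 0.4, 2, seed = 3)
  b <- sample_leroux_effects(w, 0.4, 2, seed = 3)
  expect_identical(a, b)

  expect_error(sample_leroux_effects(w, rho = 1, tau2 = 1), "singular")
  expect_error(
    sample_leroux_effects(matrix(c(0, 1, 0, 0), 2, 2), 0.5, 1), "symmetric")
  expect_error(sample_leroux_effects(w, 0.5, tau2 = -1), "positive")
})

test_that("count simulation is Poisson with the stated mean and deterministic", {
  # E = 0 forces a zero count
  truth0 <- synthetic_truth(beta = c(0, 0), rho = 0.5, tau2 = 0.1,
                            phi = c(0, 0), seed = 1)
  y0 <- simulate_counts(c(0, 10), matrix(0, 2, 1), truth0)
  expect_equal(y0[1], 0L)

  # beta = 0, phi = 0: counts/E average to 1 over many replicate areas
  n <- 10000
  truth <- synthetic_truth(beta = 0, rho = 0, tau2 = 1, phi = rep(0, n),
                           seed = 9)
  e <- rep(50, n)
  y <- simulate_counts(e, matrix(0, n, 1), truth)
  expect_lt(abs(mean(y / e) - 1), 0.01)

  # identical truth (including seed) gives identical counts
  y2 <- simulate_counts(e, matrix(0, n, 1), truth)
  expect_identical(y, y2)

  expect_error(simulate_counts(c(-1, 2), matrix(0, 2, 1), truth0),
               "non-negative")
  expect_error(synthetic_truth(beta = 0, rho = 2, tau2 = 1, phi = 0, seed = 1),
               "rho")
})

test_that("the default study is reproducible and carries its truth record", {
  st <- simulate_study(seed = 5, nrows = 6, ncols = 6)
  expect_s3_class(st, "synthetic_study")
  expect_equal(nrow(st$area_table), 36)
  expect_named(st$truth$beta, c("(Intercept)", "x1", "x2"))
  expect_equal(st$truth$rho, 0.5)
  expect_true(st$weights$symmetric)
  # x1/x2 are standardized deviation-from-mean covariates
  expect_equal(mean(st$area_table$x1), 0, tolerance = 1e-10)
  expect_equal(sd(st$area_table$x2), 1, tolerance = 1e-10)

  st2 <- simulate_study(seed = 5, nrows = 6, ncols = 6)
  expect_identical(st$area_table, st2$area_table)

  # serialization writes the five artifacts with the truth sidecar
  dir <- tempfile("study")
  files <- write_study(st, dir)
  expect_true(all(file.exists(files)))
  truth <- jsonlite::read_json(files["truth"], simplifyVector = TRUE)
  expect_equal(truth$rho, 0.5)
  expect_equal(truth$beta$x1, 0.5)
  back <- read_gal(files["gal"])
  expect_identical(back$w, st$weights$w)
  unlink(dir, recursive = TRUE)
})
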