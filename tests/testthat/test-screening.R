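make_corr_pair <- function(n = 60, r = 0.8, seed = 13) {
  # two columns with exactly the requested sample correlation
  set.seed(seed)
  a <- rnorm(n); b <- rnorm(n)
  a <- a - mean(a)
  b <- residuals(lm(b ~ a))
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  cbind(x1 = a, x2 = r * a + sqrt(1 - r^2) * b)
}

test_that("VIF matches its closed forms and flags exact collinearity", {
  # orthogonal columns: both VIF = 1
  x <- make_corr_pair(r = 0)
  expect_equal(unname(vif(x)), c(1, 1), tolerance = 1e-10)

  # two columns at correlation 0.8: VIF = 1 / (1 - 0.64)
  x8 <- make_corr_pair(r = 0.8)
  expect_equal(cor(x8)[1, 2], 0.8, tolerance = 1e-12)
  expect_equal(unname(vif(x8)), rep(1 / (1 - 0.64), 2), tolerance = 1e-6)

  # appending x3 = x1 + x2 makes everything unboundedly inflated
  x3 <- cbind(x8, x3 = x8[, 1] + x8[, 2])
  expect_true(all(is.infinite(vif(x3))))

  expect_error(vif(cbind(a = rep(1, 10), b = rnorm(10))), "constant")
  expect_error(vif(x8[, 1, drop = FALSE]), "two columns")
})

test_that("VIF is invariant to affine rescaling of columns", {
  set.seed(4)
  x <- matrix(rnorm(80), 20, 4)
  x[, 2] <- x[, 1] + 0.5 * x[, 2]
  v1 <- vif(x)
  x2 <- sweep(sweep(x, 2, c(2, -3, 0.1, 10), `*`), 2, c(1, 0, -5, 2), `+`)
  expect_equal(unname(vif(x2)), unname(v1), tolerance = 1e-8)
})

test_that("step-wise deletion drops the highest VIF until below threshold", {
  # pairwise-orthogonal design (orthogonal to the intercept too, since the
  # VIF regressions include one): nothing deleted at any threshold > 1
  set.seed(9)
  q <- qr.Q(qr(cbind(1, matrix(rnorm(100), 20, 5))))[, -1]
  colnames(q) <- paste0("v", 1:5)
  res <- vif_stepwise(q, threshold = 1.00001)
  expect_equal(res$deleted, character(0))
  expect_equal(res$retained, colnames(q))

  # one duplicated column: exactly one of the pair goes first
  dup <- cbind(q[, 1:3], v1bis = q[, 1])
  res2 <- vif_stepwise(dup, threshold = 10)
  expect_equal(res2$deleted, "v1")  # column-order tie-break on Inf VIFs
  expect_setequal(res2$retained, c("v2", "v3", "v1bis"))

  # planted near-collinear triple: deletion order matches a re-fit oracle
  set.seed(31)
  z <- matrix(rnorm(200), 40, 5)
  z[, 3] <- z[, 1] + z[, 2] + rnorm(40, 0, 0.05)
  colnames(z) <- paste0("c", 1:5)
  res3 <- vif_stepwise(z, threshold = 10)
  cur <- z
  oracle_deleted <- character(0)
  repeat {
    v <- vif(cur)
    if (max(v) <= 10) break
    j <- which.max(v)
    oracle_deleted <- c(oracle_deleted, colnames(cur)[j])
    cur <- cur[, -j, drop = FALSE]
  }
  expect_equal(res3$deleted, oracle_deleted)
  expect_equal(res3$retained, colnames(cur))
  # never deletes a column whose VIF was at or below the threshold
  for (s in seq_along(res3$trace)) {
    if (s <= length(res3$deleted))
      expect_gt(res3$trace[[s]][res3$deleted[s]], 10)
  }
  # final VIFs are all within threshold
  expect_lte(max(res3$trace[[length(res3$trace)]]), 10)

  expect_error(vif_stepwise(z, threshold = 1), "exceed 1")
})

test_that("deviation-from-the-mean centering preserves spread and skips ids", {
  d <- data.frame(area_id = c("a", "b", "c"), x = c(1, 2, 3),
                  y = c(10, 0, 5), observed = c(1, 2, 3))
  out <- center_covariates(d)
  expect_equal(out$x, c(-1, 0, 1))
  expect_equal(mean(out$y), 0)
  expect_equal(sd(out$y), sd(d$y))
  expect_equal(out$observed, d$observed)           # skipped column untouched
  expect_equal(attr(out, "centers"), c(x = 2, y = 5))

  # already-centered data is a fixed point
  again <- center_covariates(out)
  expect_equal(again$x, out$x)

  # a deprivation-like column over its observed range
  set.seed(2)
  dep <- data.frame(deprivation = pmin(pmax(rnorm(141, -0.2, 0.5), -1.15), 1.46))
  cen <- center_covariates(dep)
  expect_equal(mean(cen$deprivation), 0, tolerance = 1e-10)
  expect_equal(sd(cen$deprivation), sd(dep$deprivation))
})

test_that("correlation screening reports but never deletes", {
  x <- make_corr_pair(r = 0.5)
  rep <- correlation_screen(x, outcome = x[, 1] + rnorm(60, 0, 2))
  expect_equal(dim(rep$covariate_cor), c(2, 2))
  expect_equal(rep$covariate_cor[1, 2], 0.5, tolerance = 1e-12)
  expect_length(rep$outcome_cor, 2)
})
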