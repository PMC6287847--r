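test_that("the Leroux precision matrix follows its definition", {
  w <- rook_grid_weights(3, 3)
  # independence limit
  expect_equal(unname(leroux_precision(w, 0)), diag(9))
  # intrinsic limit: Q = D - W, all row sums zero (singular)
  q1 <- leroux_precision(w, 1)
  expect_equal(unname(rowSums(q1)), rep(0, 9))
  expect_equal(unname(q1), unname(diag(rowSums(w$w)) - w$w))
  # two connected areas at rho = 0.5
  pair <- spatial_weights(matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(unname(leroux_precision(pair, 0.5)),
               matrix(c(1, -0.5, -0.5, 1), 2, 2))
  # positive definite strictly inside the mixing range
  expect_true(all(eigen(leroux_precision(w, 0.99))$values > 0))

  expect_error(leroux_precision(matrix(c(0, 1, 0, 0), 2, 2), 0.5), "symmetric")
  expect_error(leroux_precision(w, 1.2), "rho")
})

test_that("the joint log posterior matches a term-by-term dense oracle", {
  set.seed(14)
  n <- 6
  w <- random_binary_weights(n, 0.5)
  w[1, 2] <- w[2, 1] <- 1  # ensure at least one edge
  X <- cbind(1, rnorm(n), rnorm(n))
  E <- runif(n, 20, 80)
  beta <- c(0.2, 0.5, -0.3)
  phi <- rnorm(n, 0, 0.3)
  y <- rpois(n, E * exp(drop(X %*% beta) + phi))

  for (state in list(c(0.5, 0.1), c(0.9, 0.02), c(0.1, 1.5))) {
    expect_equal(
      leroux_log_posterior(beta, phi, state[1], state[2], y, X, E,
                           spatial_weights(w)),
      log_posterior_oracle(beta, phi, state[1], state[2], y, X, E, w),
      tolerance = 1e-10)
  }

  # moving a fitted mean toward its observation raises the likelihood term
  better <- leroux_log_posterior(beta, phi, 0.5, 0.1, y, X, E,
                                 spatial_weights(w))
  mle_beta <- coef(glm(y ~ X[, 2] + X[, 3] + offset(log(E) + phi),
                       family = poisson))
  best <- leroux_log_posterior(unname(mle_beta), phi, 0.5, 0.1, y, X, E,
                               spatial_weights(w))
  expect_gt(best, better - 1e-9)

  # phi = 0: the prior quadratic form contributes exactly zero
  q <- leroux_precision(spatial_weights(w), 0.5)
  lp0 <- leroux_log_posterior(beta, rep(0, n), 0.5, 0.1, y, X, E,
                              spatial_weights(w))
  manual <- sum(y * (log(E) + drop(X %*% beta)) -
                E * exp(drop(X %*% beta))) +
    0.5 * determinant(q)$modulus[1] - n / 2 * log(0.1) -
    sum(beta^2) / (2 * 1e5) - 3 / 2 * log(2 * pi * 1e5) +
    1 * log(0.01) - lgamma(1) - 2 * log(0.1) - 0.01 / 0.1
  expect_equal(lp0, manual, tolerance = 1e-10)

  expect_error(
    leroux_log_posterior(beta, phi, 1.5, 0.1, y, X, E, spatial_weights(w)),
    "rho")
  expect_error(
    leroux_log_posterior(beta, phi, 0.5, -1, y, X, E, spatial_weights(w)),
    "tau2")
})

test_that("tau2 Gibbs draws agree with the closed-form inverse gamma", {
  w <- rook_grid_weights(4, 4)
  set.seed(6)
  phi <- rnorm(16, 0, 0.5)
  res <- draw_tau2_conditional(phi, w, rho = 0.6, ndraws = 50000, seed = 99)
  a <- res$shape; b <- res$scale
  q <- leroux_precision(w, 0.6)
  expect_equal(a, 1 + 8)
  expect_equal(b, 0.01 + drop(phi %*% q %*% phi) / 2, tolerance = 1e-12)
  # IG moments: mean b/(a-1), variance b^2 / ((a-1)^2 (a-2))
  expect_equal(mean(res$draws), b / (a - 1), tolerance = 0.02)
  expect_equal(var(res$draws), b^2 / ((a - 1)^2 * (a - 2)), tolerance = 0.05)
})

test_that("with phi = 0 the posterior mode of beta is the Poisson IRLS fit", {
  st <- simulate_study(seed = 23, nrows = 6, ncols = 6, tau2 = 0.01)
  d <- st$area_table
  X <- cbind(1, d$x1, d$x2)
  flat <- leroux_prior(beta_var = Inf)
  nll <- function(b)
    -leroux_log_posterior(b, rep(0, 36), 0.5, 0.1, d$observed, X, d$expected,
                          st$weights, prior = flat)
  gr <- function(b)
    -drop(crossprod(X, d$observed - d$expected * exp(drop(X %*% b))))
  opt <- optim(c(0, 0, 0), nll, gr, method = "BFGS",
               control = list(reltol = 1e-15, maxit = 500))
  oracle <- glm(observed ~ x1 + x2 + offset(log(expected)), data = d,
                family = poisson)
  expect_equal(unname(opt$par), unname(coef(oracle)), tolerance = 1e-6)
})

test_that("the sampler is deterministic, well-tuned and internally consistent", {
  st <- simulate_study(seed = 31, nrows = 7, ncols = 7)
  mc <- mcmc_control(n_iter = 6000, n_burnin = 2000, thin = 2, seed = 11)
  fit <- leroux_car(observed ~ x1 + x2, data = st$area_table,
                    weights = st$weights, expected = "expected", mcmc = mc)
  fit2 <- leroux_car(observed ~ x1 + x2, data = st$area_table,
                     weights = st$weights, expected = "expected", mcmc = mc)
  expect_identical(fit$samples, fit2$samples)

  # acceptance rates for every Metropolis block within the tuned band
  expect_true(all(fit$accept >= 0.2 & fit$accept <= 0.6))

  # summary ordering: lower <= mean <= upper for every parameter
  s <- fit$summary
  expect_true(all(s[, "2.5%"] <= s[, "mean"] & s[, "mean"] <= s[, "97.5%"]))

  # relative risks are the exp of the coefficient percentile summaries
  rr <- relative_risks(fit)
  b1 <- fit$samples$beta[, "x1"]
  expect_equal(rr$estimate[rr$variable == "x1"], exp(mean(b1)))
  expect_equal(rr$lower[rr$variable == "x1"],
               exp(unname(quantile(b1, 0.025))))
  expect_equal(rr$upper[rr$variable == "x1"],
               exp(unname(quantile(b1, 0.975))))
  # monotone-transform check: order-statistic quantiles commute with exp
  expect_equal(exp(quantile(b1, c(0.025, 0.975), type = 1)),
               quantile(exp(b1), c(0.025, 0.975), type = 1),
               tolerance = 1e-12)

  # residual check runs the same permutation engine as the autocorrelation
  # module: same seed, same p
  r <- residuals(fit, "pearson")
  direct <- moran_mc_test(r, st$weights, nperm = 199, seed = 77)
  via_fit <- residual_moran_check(fit, nperm = 199, seed = 77)
  expect_identical(direct$p_value, via_fit$p_value)
  expect_identical(direct$statistic, via_fit$statistic)

  # methods behave
  expect_length(coef(fit), 3)
  expect_length(fitted(fit), 49)
  expect_equal(residuals(fit, "response"), st$area_table$observed - fitted(fit))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(49, 3))
})

test_that("input validation refuses unusable models", {
  st <- simulate_study(seed = 2, nrows = 4, ncols = 4)
  d <- st$area_table
  expect_error(
    leroux_car(observed ~ x1 - 1, data = d, weights = st$weights,
               expected = "expected"), "intercept")
  d0 <- d; d0$expected[3] <- 0
  expect_error(
    leroux_car(observed ~ x1, data = d0, weights = st$weights,
               expected = "expected"), "positive")
  wk <- knn_weights(data.frame(d$area_id, st$lattice$centroids), k = 3)
  expect_error(
    leroux_car(observed ~ x1, data = d, weights = wk, expected = "expected"),
    "symmetric")
})

test_that("fixing rho at zero reproduces an iid-random-effect Poisson GLMM", {
  skip_if_not_installed("lme4")
  st <- simulate_study(seed = 41, rho = 0, tau2 = 0.05)
  d <- st$area_table
  mc <- mcmc_control(n_iter = 12000, n_burnin = 3000, thin = 3, seed = 8,
                     fix_rho = 0)
  fit <- leroux_car(observed ~ x1 + x2, data = d, weights = st$weights,
                    expected = "expected", mcmc = mc)
  d$area <- factor(seq_len(nrow(d)))
  gl <- lme4::glmer(observed ~ x1 + x2 + (1 | area),
                    offset = log(d$expected), data = d, family = poisson)
  fe <- lme4::fixef(gl)
  expect_equal(unname(coef(fit)[c("x1", "x2")]),
               unname(fe[c("x1", "x2")]), tolerance = 0.05)
  # variance component in the same neighbourhood
  vc <- as.numeric(lme4::VarCorr(gl)$area)
  expect_equal(mean(fit$samples$tau2), vc, tolerance = 0.5)
})
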