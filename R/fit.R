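#' Bayesian Poisson regression with Leroux CAR spatial random effects
#'
#' Fits the areal disease-mapping model
#' `y_i ~ Poisson(E_i * exp(x_i' beta + phi_i))` where `E_i` are expected
#' counts entering as a fixed offset and `phi` carries the Leroux
#' conditional autoregressive prior `N(0, tau2 * Q(rho, W)^{-1})`,
#' `Q = rho (D - W) + (1 - rho) I` (see [leroux_precision()]).  Priors:
#' zero-mean Gaussian on each coefficient, uniform(0, 1) on `rho`,
#' inverse-gamma on `tau2`.  A single-chain Metropolis-within-Gibbs sampler
#' is run: random-walk block updates for `beta`, per-area random-walk
#' updates for `phi` (re-centred to mean zero each sweep, the mean absorbed
#' by the intercept), a conjugate Gibbs draw for `tau2` and a logit-scale
#' random walk for `rho`; proposal scales adapt during burn-in only.
#'
#' @param formula model formula, e.g. `observed ~ x1 + x2`.  An intercept is
#'   required (the spatial effects are centered against it).  Factor
#'   covariates expand to indicator contrasts against their reference level.
#' @param data data frame containing the formula variables and, if
#'   `expected` is a name, the expected-count column.
#' @param weights symmetric binary `spatial_weights` over the rows of
#'   `data` (same order).  Asymmetric (e.g. raw k-NN) weights are an error:
#'   pass them through [symmetrize()] first.
#' @param expected expected counts: a numeric vector or the name of a column
#'   of `data`.  All values must be positive (areas with zero expected
#'   counts cannot be modelled on the relative scale and must be removed
#'   explicitly).
#' @param prior a [leroux_prior()].
#' @param mcmc an [mcmc_control()].
#' @param verbose print a one-line progress note.
#' @return object of class `"leroux_car"` with retained posterior samples
#'   (`$samples$beta`, `$samples$phi`, `$samples$rho`, `$samples$tau2`),
#'   posterior summary table, fitted values, Pearson residuals, Metropolis
#'   acceptance rates, Geweke convergence z-scores and the call.
#' @seealso [summary.leroux_car()], [relative_risks()],
#'   [residual_moran_check()]
#' @examples
#' \donttest{
#' study <- simulate_study(seed = 7, nrows = 6, ncols = 6)
#' fit <- leroux_car(observed ~ x1 + x2, data = study$area_table,
#'                   weights = study$weights, expected = "expected",
#'                   mcmc = mcmc_control(n_iter = 2000, n_burnin = 500))
#' summary(fit)
#' }
#' @export
leroux_car <- function(formula, data, weights, expected,
                       prior = leroux_prior(), mcmc = mcmc_control(),
                       verbose = FALSE) {
  cl <- match.call()
  stopifnot(inherits(prior, "leroux_prior"), inherits(mcmc, "mcmc_control"))
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  if (!"(Intercept)" %in% colnames(X))
    stop("the model requires an intercept (spatial effects are centered against it)",
         call. = FALSE)
  n <- length(y)
  if (any(y < 0) || any(y != round(y)))
    stop("the response must be non-negative counts", call. = FALSE)

  if (is.character(expected) && length(expected) == 1L) {
    if (!expected %in% names(data))
      stop("expected-count column '", expected, "' not found in 'data'", call. = FALSE)
    expected <- data[[expected]]
  }
  if (length(expected) != n)
    stop("'expected' length must match the data", call. = FALSE)
  if (any(!is.finite(expected)) || any(expected <= 0))
    stop("all expected counts must be positive; remove E = 0 areas before fitting",
         call. = FALSE)

  w <- weights_matrix(weights)
  if (nrow(w) != n)
    stop("weights order must match the data rows", call. = FALSE)
  if (!isSymmetric(unname(w)))
    stop("the CAR prior requires symmetric weights; see symmetrize()", call. = FALSE)
  if (!all(w %in% c(0, 1)))
    stop("the CAR prior expects binary weights", call. = FALSE)

  # GLM initialization: posterior-mode-like start and coefficient-wise
  # proposal scales from the Fisher information
  init <- stats::glm.fit(X, y, offset = log(expected), family = stats::poisson())
  beta0 <- init$coefficients
  if (anyNA(beta0))
    stop("design matrix is rank-deficient; screen covariates first", call. = FALSE)
  xtwx <- crossprod(X * sqrt(init$weights), X)
  prop_sd <- sqrt(diag(chol2inv(chol(xtwx))))

  d <- rowSums(w)
  lambda <- eigen(diag(d) - w, symmetric = TRUE, only.values = TRUE)$values
  # CSR adjacency (0-based)
  nb <- apply(w > 0, 1, which, simplify = FALSE)
  rowstart <- c(0L, cumsum(lengths(nb)))
  adj <- as.integer(unlist(nb, use.names = FALSE) - 1L)
  adjw <- w[cbind(rep(seq_len(n), lengths(nb)), unlist(nb, use.names = FALSE))]

  fix_rho <- !is.null(mcmc$fix_rho)
  rho_init <- if (fix_rho) mcmc$fix_rho else 0.5

  if (verbose)
    message("Leroux CAR MCMC: ", mcmc$n_iter, " iterations (",
            mcmc$n_burnin, " burn-in, thin ", mcmc$thin, "), n = ", n)
  set.seed(mcmc$seed)
  raw <- leroux_mcmc(as.numeric(y), X, log(expected),
                     adj, as.numeric(adjw), rowstart, d, lambda,
                     beta0, prop_sd, prior$beta_var,
                     prior$tau2_shape, prior$tau2_scale,
                     mcmc$n_iter, mcmc$n_burnin, mcmc$thin,
                     mcmc$scale_beta, mcmc$scale_phi, mcmc$scale_rho,
                     mcmc$adapt, rho_init, 0.1, fix_rho)

  colnames(raw$beta) <- colnames(X)
  colnames(raw$phi) <- weights_ids(weights, n)
  samples <- list(beta = raw$beta, phi = raw$phi,
                  rho = as.numeric(raw$rho), tau2 = as.numeric(raw$tau2))

  eta <- tcrossprod(raw$beta, X) + raw$phi      # nkeep x n
  mu <- exp(sweep(eta, 2, log(expected), `+`))
  fitted <- colMeans(mu)
  pearson <- (y - fitted) / sqrt(fitted)

  pars <- cbind(raw$beta, tau2 = samples$tau2,
                rho = if (fix_rho) NULL else samples$rho)
  stats_tab <- t(apply(pars, 2, function(s)
    c(mean = mean(s), sd = stats::sd(s),
      `2.5%` = unname(stats::quantile(s, 0.025)),
      `97.5%` = unname(stats::quantile(s, 0.975)),
      geweke_z = geweke_z(s))))

  out <- list(call = cl, formula = formula, n = n, y = as.numeric(y), X = X,
              expected = as.numeric(expected), weights = weights,
              prior = prior, mcmc = mcmc, fix_rho = mcmc$fix_rho,
              samples = samples, summary = stats_tab,
              fitted_values = fitted, residuals_pearson = pearson,
              accept = raw$accept, scales = raw$scales)
  class(out) <- "leroux_car"
  out
}

# Geweke convergence diagnostic: z-score comparing the mean of the first 10%
# of a chain with the mean of its last 50%, each variance estimated by
# non-overlapping batch means (a simple spectral-density-at-zero surrogate).
geweke_z <- function(s, frac1 = 0.1, frac2 = 0.5) {
  m <- length(s)
  a <- s[seq_len(max(2, floor(frac1 * m)))]
  b <- s[seq.int(m - floor(frac2 * m) + 1, m)]
  bm_var <- function(v) {
    nb <- max(2L, floor(sqrt(length(v))))
    bs <- floor(length(v) / nb)
    means <- vapply(seq_len(nb),
                    function(k) mean(v[((k - 1) * bs + 1):(k * bs)]), numeric(1))
    stats::var(means) / nb
  }
  va <- bm_var(a); vb <- bm_var(b)
  if (va + vb == 0) return(0)
  (mean(a) - mean(b)) / sqrt(va + vb)
}

#' @export
print.leroux_car <- function(x, digits = 4, ...) {
  cat("Poisson log-linear model with Leroux CAR spatial random effects\n")
  cat("Call: ", deparse(x$call), "\n\n")
  cat("Areas:", x$n, " retained samples:", length(x$samples$tau2), "\n")
  print(round(x$summary, digits))
  invisible(x)
}

#' Posterior summary of a Leroux CAR fit
#'
#' @param object a `"leroux_car"` fit.
#' @param ... unused.
#' @return object of class `"summary.leroux_car"`: the posterior table
#'   (mean, sd, 2.5% and 97.5% percentiles, Geweke z per parameter),
#'   acceptance rates and sampler settings.
#' @export
summary.leroux_car <- function(object, ...) {
  structure(list(call = object$call, table = object$summary,
                 accept = object$accept, n = object$n,
                 mcmc = object$mcmc, fix_rho = object$fix_rho),
            class = "summary.leroux_car")
}

#' @export
print.summary.leroux_car <- function(x, digits = 4, ...) {
  cat("Leroux CAR Poisson model —", x$n, "areas\n")
  cat(sprintf("MCMC: %d iterations, %d burn-in, thin %d, seed %d\n",
              x$mcmc$n_iter, x$mcmc$n_burnin, x$mcmc$thin, x$mcmc$seed))
  if (!is.null(x$fix_rho)) cat("rho fixed at", x$fix_rho, "\n")
  cat("\nPosterior summaries (95% credible intervals):\n")
  print(round(x$table, digits))
  cat("\nMetropolis acceptance rates:",
      paste(names(x$accept), round(x$accept, 2), collapse = "  "), "\n")
  invisible(x)
}

#' @export
coef.leroux_car <- function(object, ...) {
  colMeans(object$samples$beta)
}

#' @export
fitted.leroux_car <- function(object, ...) {
  object$fitted_values
}

#' @export
residuals.leroux_car <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  switch(type,
         pearson = object$residuals_pearson,
         response = object$y - object$fitted_values)
}

#' @export
plot.leroux_car <- function(x, which = NULL, ...) {
  pars <- cbind(x$samples$beta, tau2 = x$samples$tau2,
                rho = if (is.null(x$fix_rho)) x$samples$rho else NULL)
  if (is.null(which)) which <- colnames(pars)
  old <- graphics::par(mfrow = c(length(which), 1),
                       mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(old))
  for (nm in which) {
    graphics::plot(pars[, nm], type = "l", ylab = nm, xlab = "",
                   main = paste("trace:", nm), ...)
  }
  invisible(x)
}

#' Posterior predictive count simulation
#'
#' Draws replicate count vectors from the posterior predictive distribution
#' (one retained posterior sample of `(beta, phi)` per replicate).
#'
#' @param object a `"leroux_car"` fit.
#' @param nsim number of replicate datasets.
#' @param seed optional seed.
#' @param ... unused.
#' @return n x nsim integer matrix of simulated counts.
#' @export
simulate.leroux_car <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  nkeep <- nrow(object$samples$beta)
  idx <- sample.int(nkeep, nsim, replace = nsim > nkeep)
  out <- vapply(idx, function(k) {
    eta <- drop(object$X %*% object$samples$beta[k, ]) + object$samples$phi[k, ]
    stats::rpois(object$n, object$expected * exp(eta))
  }, numeric(object$n))
  matrix(as.integer(out), nrow = object$n,
         dimnames = list(rownames(object$X), NULL))
}

#' Relative-risk table from a fitted Leroux model
#'
#' Exponentiates the regression-coefficient posterior: each row gives the
#' multiplicative relative risk per unit increase of a (centered) continuous
#' covariate, or versus the reference level for factor contrasts, with its
#' 95% credible interval and a flag marking intervals that exclude the null
#' (the coefficient CrI excludes zero, equivalently the RR CrI excludes 1).
#' Posterior summaries of the spatial variance `tau2` and mixing `rho` are
#' appended on their natural scale.
#'
#' @param object a `"leroux_car"` fit.
#' @param digits optional rounding for display (`NULL` = none).
#' @return data frame with columns `variable`, `estimate` (posterior-mean RR
#'   or natural-scale mean for `tau2`/`rho`), `lower`, `upper`,
#'   `excludes_null`.
#' @export
relative_risks <- function(object, digits = NULL) {
  stopifnot(inherits(object, "leroux_car"))
  bs <- object$samples$beta
  vars <- setdiff(colnames(bs), "(Intercept)")
  rows <- lapply(vars, function(v) {
    q <- stats::quantile(bs[, v], c(0.025, 0.975))
    data.frame(variable = v, estimate = exp(mean(bs[, v])),
               lower = exp(q[[1]]), upper = exp(q[[2]]),
               excludes_null = q[[1]] > 0 || q[[2]] < 0,
               stringsAsFactors = FALSE)
  })
  t2 <- object$samples$tau2
  qt <- stats::quantile(t2, c(0.025, 0.975))
  rows[[length(rows) + 1L]] <- data.frame(
    variable = "tau2 (spatial variance)", estimate = mean(t2),
    lower = qt[[1]], upper = qt[[2]], excludes_null = NA,
    stringsAsFactors = FALSE)
  if (is.null(object$fix_rho)) {
    r <- object$samples$rho
    qr <- stats::quantile(r, c(0.025, 0.975))
    rows[[length(rows) + 1L]] <- data.frame(
      variable = "rho (spatial correlation)", estimate = mean(r),
      lower = qr[[1]], upper = qr[[2]], excludes_null = NA,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(digits))
    out[2:4] <- lapply(out[2:4], round, digits = digits)
  out
}

#' Residual spatial autocorrelation check
#'
#' Applies the Moran's I Monte-Carlo permutation test to the posterior-mean
#' Pearson residuals `(y_i - mu_i) / sqrt(mu_i)` of a fitted model.  A
#' non-significant result indicates the spatial random effects have absorbed
#' the residual spatial structure.
#'
#' @param object a `"leroux_car"` fit.
#' @param weights weights for the test; defaults to the fit's own weights.
#' @param nperm permutations (default 999).
#' @param alternative passed to [moran_mc_test()] (default `"greater"`).
#' @param seed optional seed.
#' @return a `"moran_test"` object.
#' @export
residual_moran_check <- function(object, weights = object$weights,
                                 nperm = 999, alternative = "greater",
                                 seed = NULL) {
  stopifnot(inherits(object, "leroux_car"))
  r <- residuals(object, type = "pearson")
  if (stats::sd(r) == 0)
    stop("residuals are constant: Moran's I undefined", call. = FALSE)
  moran_mc_test(r, weights, nperm = nperm, alternative = alternative,
                seed = seed)
}
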