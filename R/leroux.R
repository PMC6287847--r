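#' Leroux CAR precision matrix
#'
#' The Leroux prior for area effects phi is a zero-mean Gaussian Markov
#' random field with precision `Q(rho, W) / tau2` where
#' `Q = rho * (D - W) + (1 - rho) * I`, `W` the symmetric binary adjacency
#' and `D = diag(rowSums(W))`.  Its full conditionals are
#' `phi_i | phi_-i ~ N(rho * sum_j w_ij phi_j / (rho * w_i+ + 1 - rho),
#' tau2 / (rho * w_i+ + 1 - rho))`: `rho = 0` gives independent effects,
#' `rho = 1` the intrinsic CAR (singular `Q`, every row summing to zero).
#' `Q` is positive definite for `rho < 1`.
#'
#' @param weights symmetric binary `spatial_weights` (or matrix).
#' @param rho spatial mixing parameter in `[0, 1]`.
#' @return n x n symmetric precision structure matrix `Q(rho, W)`.
#' @export
leroux_precision <- function(weights, rho) {
  w <- weights_matrix(weights)
  if (!isSymmetric(unname(w)))
    stop("the CAR prior requires symmetric weights; see symmetrize()", call. = FALSE)
  if (!is.numeric(rho) || length(rho) != 1L || rho < 0 || rho > 1)
    stop("'rho' must be in [0, 1]", call. = FALSE)
  d <- rowSums(w)
  q <- -rho * w
  diag(q) <- rho * d + (1 - rho)
  dimnames(q) <- dimnames(w)
  q
}

#' Sample Leroux CAR random effects
#'
#' Draws from the proper Leroux Gaussian Markov random field
#' `phi ~ N(0, tau2 * Q(rho, W)^{-1})` via the Cholesky factor of `Q`
#' (`phi = sqrt(tau2) * R^{-1} z`, `R'R = Q`, `z ~ N(0, I)`).  Requires
#' `rho < 1` so the joint distribution is proper.
#'
#' @inheritParams leroux_precision
#' @param rho spatial mixing in `[0, 1)`.
#' @param tau2 positive conditional-variance scale.
#' @param seed optional integer seed (draws are reproducible given it).
#' @param ndraws number of independent draws.
#' @return numeric vector of length n (`ndraws = 1`) or an n x ndraws matrix.
#' @export
sample_leroux_effects <- function(weights, rho, tau2, seed = NULL, ndraws = 1) {
  if (!is.numeric(tau2) || length(tau2) != 1L || tau2 <= 0)
    stop("'tau2' must be positive", call. = FALSE)
  if (rho >= 1)
    stop("'rho' must be below 1: the intrinsic limit has a singular precision",
         call. = FALSE)
  q <- leroux_precision(weights, rho)
  r <- chol(q)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(q)
  z <- matrix(stats::rnorm(n * ndraws), n, ndraws)
  phi <- sqrt(tau2) * backsolve(r, z)
  rownames(phi) <- rownames(q)
  if (ndraws == 1) drop(phi) else phi
}

#' Leroux model prior specification
#'
#' @param beta_var prior variance of each regression coefficient
#'   (zero-mean Gaussian; default 1e5, effectively flat; `Inf` gives a flat
#'   prior).
#' @param tau2_shape,tau2_scale inverse-gamma hyperparameters for `tau2`,
#'   density proportional to `tau2^-(shape+1) * exp(-scale / tau2)`
#'   (default shape 1, scale 0.01).  `rho` always carries a uniform prior
#'   on the open interval (0, 1).
#' @return list of class `"leroux_prior"`.
#' @export
leroux_prior <- function(beta_var = 1e5, tau2_shape = 1, tau2_scale = 0.01) {
  if (beta_var <= 0) stop("'beta_var' must be positive", call. = FALSE)
  if (tau2_shape <= 0 || tau2_scale <= 0)
    stop("inverse-gamma hyperparameters must be positive", call. = FALSE)
  structure(list(beta_var = beta_var, tau2_shape = tau2_shape,
                 tau2_scale = tau2_scale),
            class = "leroux_prior")
}

#' MCMC settings for the Leroux model
#'
#' Desk-scale default: 20,000 iterations, 5,000 burn-in, thinning 5 — enough
#' for the moderate posteriors of ~150-area problems.  `preset = "long"`
#' selects the heavy single-chain schedule of 500,000 iterations with
#' 100,000 burn-in used for production disease-mapping runs.
#'
#' @param n_iter total MCMC iterations.
#' @param n_burnin burn-in iterations discarded (must be < `n_iter`).
#' @param thin retain every `thin`-th post-burn-in sweep.
#' @param seed integer RNG seed; the sampler is deterministic given it.
#' @param adapt adapt Metropolis proposal scales during burn-in only.
#' @param scale_beta,scale_phi,scale_rho initial proposal scales.
#' @param fix_rho optional value in `[0, 1)` at which `rho` is held fixed
#'   (e.g. `0` for independent random effects); `NULL` samples it.
#' @param preset `"desk"` (default sizes above) or `"long"`.
#' @return list of class `"mcmc_control"`.
#' @export
mcmc_control <- function(n_iter = 20000, n_burnin = 5000, thin = 5,
                         seed = 1L, adapt = TRUE,
                         scale_beta = 0.3, scale_phi = 0.5, scale_rho = 1,
                         fix_rho = NULL, preset = c("desk", "long")) {
  preset <- match.arg(preset)
  if (preset == "long") {
    if (missing(n_iter)) n_iter <- 500000
    if (missing(n_burnin)) n_burnin <- 100000
    if (missing(thin)) thin <- 50
  }
  if (n_burnin >= n_iter) stop("'n_burnin' must be below 'n_iter'", call. = FALSE)
  if (thin < 1) stop("'thin' must be >= 1", call. = FALSE)
  if (!is.null(fix_rho) && (fix_rho < 0 || fix_rho >= 1))
    stop("'fix_rho' must lie in [0, 1)", call. = FALSE)
  structure(list(n_iter = as.integer(n_iter), n_burnin = as.integer(n_burnin),
                 thin = as.integer(thin), seed = as.integer(seed),
                 adapt = isTRUE(adapt), scale_beta = scale_beta,
                 scale_phi = scale_phi, scale_rho = scale_rho,
                 fix_rho = fix_rho, preset = preset),
            class = "mcmc_control")
}

#' Joint log-posterior of the Leroux Poisson model
#'
#' Evaluates, up to the additive constant `-sum(log(y!))`, the joint
#' log-posterior of `(beta, phi, rho, tau2)` under the Poisson likelihood
#' `y_i ~ Poisson(E_i * exp(x_i' beta + phi_i))`, the Leroux GMRF prior on
#' `phi`, the Gaussian prior on `beta`, uniform(0,1) on `rho` and
#' inverse-gamma on `tau2`:
#'
#' `sum_i [y_i (log E_i + x_i' beta + phi_i) - E_i e^{x_i' beta + phi_i}]
#'  + 0.5 log|Q(rho)| - n/2 log tau2 - phi' Q phi / (2 tau2) + log-priors`.
#'
#' A dense, term-by-term evaluation kept deliberately simple so it can serve
#' as the reference the MCMC kernel is validated against.
#'
#' @param beta,phi,rho,tau2 model state (`tau2 > 0`, `rho` in (0, 1)).
#' @param y observed counts.
#' @param X design matrix (n x p, including the intercept column).
#' @param expected expected counts `E_i > 0` (the offset is `log(expected)`).
#' @param weights symmetric binary `spatial_weights`.
#' @param prior a [leroux_prior()].
#' @return scalar log-posterior density (unnormalized).
#' @export
leroux_log_posterior <- function(beta, phi, rho, tau2, y, X, expected,
                                 weights, prior = leroux_prior()) {
  if (tau2 <= 0 || rho <= 0 || rho >= 1)
    stop("'tau2' must be positive and 'rho' inside (0, 1)", call. = FALSE)
  X <- as.matrix(X)
  n <- length(y)
  if (length(phi) != n || nrow(X) != n || length(expected) != n)
    stop("state dimensions do not match the data", call. = FALSE)
  eta <- log(expected) + drop(X %*% beta) + phi
  loglik <- sum(y * eta - exp(eta))
  q <- leroux_precision(weights, rho)
  logdet <- as.numeric(determinant(q, logarithm = TRUE)$modulus)
  quad <- drop(crossprod(phi, q %*% phi))
  lp_phi <- 0.5 * logdet - n / 2 * log(tau2) - quad / (2 * tau2)
  lp_beta <- if (is.finite(prior$beta_var))
    -sum(beta^2) / (2 * prior$beta_var) - length(beta) / 2 * log(2 * pi * prior$beta_var)
  else 0
  a <- prior$tau2_shape; b <- prior$tau2_scale
  lp_tau2 <- a * log(b) - lgamma(a) - (a + 1) * log(tau2) - b / tau2
  loglik + lp_phi + lp_beta + lp_tau2   # log p(rho) = 0 on (0,1)
}

#' Gibbs draws from the tau2 full conditional
#'
#' Given `phi`, the Leroux model's variance parameter has the conjugate
#' full conditional `tau2 | phi ~ IG(shape + n/2, scale + phi' Q phi / 2)`.
#' Exposed so the conjugacy of the Gibbs step can be checked against the
#' closed-form inverse-gamma moments.
#'
#' @inheritParams leroux_log_posterior
#' @param ndraws number of draws.
#' @param seed optional seed.
#' @return list with `draws` (numeric vector), `shape` and `scale` of the
#'   full conditional.
#' @export
draw_tau2_conditional <- function(phi, weights, rho, prior = leroux_prior(),
                                  ndraws = 1, seed = NULL) {
  q <- leroux_precision(weights, rho)
  n <- length(phi)
  shape <- prior$tau2_shape + n / 2
  scale <- prior$tau2_scale + drop(crossprod(phi, q %*% phi)) / 2
  if (!is.null(seed)) set.seed(seed)
  list(draws = 1 / stats::rgamma(ndraws, shape = shape, rate = scale),
       shape = shape, scale = scale)
}
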