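# Independent reference implementations used to validate the package's
# statistics.  Deliberately written as naive loops / dense linear algebra so
# they share no code path with the implementation under test.

moran_bruteforce <- function(x, w) {
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  for (i in seq_len(n))
    for (j in seq_len(n))
      num <- num + w[i, j] * z[i] * z[j]
  (n / sum(w)) * num / sum(z^2)
}

local_moran_bruteforce <- function(x, w) {
  n <- length(x)
  z <- x - mean(x)
  m2 <- sum(z^2) / n
  li <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(n)) s <- s + w[i, j] * z[j]
    li[i] <- z[i] / m2 * s
  }
  li
}

# dense term-by-term log posterior (unnormalized, same constant conventions
# as leroux_log_posterior): Poisson + Leroux GMRF + Gaussian beta + IG tau2
log_posterior_oracle <- function(beta, phi, rho, tau2, y, X, E, w,
                                 beta_var = 1e5, a = 1, b = 0.01) {
  n <- length(y)
  ll <- 0
  for (i in seq_len(n)) {
    eta <- log(E[i]) + sum(X[i, ] * beta) + phi[i]
    ll <- ll + y[i] * eta - exp(eta)
  }
  q <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      q[i, j] <- if (i == j) rho * sum(w[i, ]) + (1 - rho) else -rho * w[i, j]
    }
  }
  logdet <- sum(log(eigen(q, symmetric = TRUE, only.values = TRUE)$values))
  quad <- 0
  for (i in seq_len(n))
    for (j in seq_len(n)) quad <- quad + phi[i] * q[i, j] * phi[j]
  lp <- ll + 0.5 * logdet - n / 2 * log(tau2) - quad / (2 * tau2)
  lp <- lp - sum(beta^2) / (2 * beta_var) -
    length(beta) / 2 * log(2 * pi * beta_var)
  lp + a * log(b) - lgamma(a) - (a + 1) * log(tau2) - b / tau2
}

# random symmetric binary weights over n areas (connected not guaranteed;
# no self-neighbours)
random_binary_weights <- function(n, p = 0.3) {
  w <- matrix(rbinom(n * n, 1, p), n, n)
  w <- pmax(w, t(w))
  diag(w) <- 0
  w
}

rook_grid_weights <- function(nr, nc) {
  lattice_weights(make_grid_lattice(nr, nc))
}
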