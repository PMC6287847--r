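#' Global Moran's I
#'
#' `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with `z = x - mean(x)`
#' and `S0 = sum_ij w_ij`.  Positive values indicate that neighbouring areas
#' carry similar values (clustering), negative values that neighbours are
#' systematically dissimilar.  The statistic is invariant to adding a
#' constant to `x` and to positive rescaling.
#'
#' @param x numeric per-area values (length n >= 3, non-constant).
#' @param weights `spatial_weights` or weight matrix in the same area order.
#' @return the Moran's I statistic (scalar).
#' @seealso [moran_mc_test()] for permutation inference, [local_moran()].
#' @export
global_moran <- function(x, weights) {
  w <- weights_matrix(weights)
  n <- length(x)
  if (nrow(w) != n) stop("'x' length must match weights order", call. = FALSE)
  if (n < 2) stop("global Moran's I needs at least 2 areas", call. = FALSE)
  z <- x - mean(x)
  m2 <- sum(z^2)
  if (m2 == 0) stop("'x' is constant: Moran's I undefined (zero variance)",
                    call. = FALSE)
  s0 <- sum(w)
  (n / s0) * drop(crossprod(z, w %*% z)) / m2
}

#' Monte-Carlo permutation test for global Moran's I
#'
#' Compares the observed statistic with its distribution under `nperm`
#' random relabellings of `x` over the areas.  The pseudo p-value is
#' `(m + 1) / (nperm + 1)` where `m` counts permuted statistics at least as
#' extreme as the observed one; its smallest attainable value is
#' `1 / (nperm + 1)`.  Under `alternative = "two-sided"` extremeness is
#' measured by the folded statistic `|I - mean(I_perm)|`.
#'
#' @inheritParams global_moran
#' @param nperm number of permutations (default 999).
#' @param alternative `"greater"` (clustering, default) or `"two-sided"`.
#' @param seed optional integer seed making the permutations reproducible.
#' @return object of class `"moran_test"`: list with `statistic`,
#'   `expectation` (`-1/(n-1)`), `p_value`, `z_score`, `nperm`,
#'   `alternative`, and the permuted statistics `sim`.
#' @export
moran_mc_test <- function(x, weights, nperm = 999,
                          alternative = c("greater", "two-sided"),
                          seed = NULL) {
  alternative <- match.arg(alternative)
  if (nperm < 19) stop("'nperm' must be at least 19", call. = FALSE)
  w <- weights_matrix(weights)
  n <- length(x)
  if (n < 3) stop("inference needs at least 3 areas", call. = FALSE)
  z <- x - mean(x)
  if (sum(z^2) == 0)
    stop("'x' is constant: Moran's I undefined (zero variance)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  obs <- global_moran(x, w)
  # All permutations at once: I_perm = (n/S0) * colSums(Z * (W Z)) / colSums(Z^2)
  perm <- vapply(seq_len(nperm), function(i) sample.int(n), integer(n))
  zmat <- matrix(z[perm], nrow = n)
  s0 <- sum(w)
  sim <- (n / s0) * colSums(zmat * (w %*% zmat)) / colSums(zmat^2)

  m <- switch(alternative,
    greater = sum(sim >= obs),
    `two-sided` = {
      ctr <- mean(sim)
      sum(abs(sim - ctr) >= abs(obs - ctr))
    }
  )
  structure(
    list(statistic = obs, expectation = -1 / (n - 1),
         p_value = (m + 1) / (nperm + 1),
         z_score = (obs - mean(sim)) / stats::sd(sim),
         nperm = nperm, alternative = alternative, sim = sim),
    class = "moran_test"
  )
}

#' @export
print.moran_test <- function(x, ...) {
  cat("Moran's I permutation test (", x$nperm, " permutations, ",
      x$alternative, ")\n", sep = "")
  cat(sprintf("  I = %.4f  E[I] = %.4f  z = %.2f  pseudo p = %.4g\n",
              x$statistic, x$expectation, x$z_score, x$p_value))
  invisible(x)
}

#' Local Moran's I (LISA)
#'
#' Per-area decomposition `I_i = (z_i / m2) * sum_j w_ij z_j` with
#' `m2 = sum_k z_k^2 / n`, satisfying `sum_i I_i = S0 * I` where `I` is the
#' global statistic.  Areas with an all-zero weight row get `I_i = 0`.
#'
#' @inheritParams global_moran
#' @return numeric vector of local statistics, named by area id.
#' @export
local_moran <- function(x, weights) {
  w <- weights_matrix(weights)
  n <- length(x)
  if (nrow(w) != n) stop("'x' length must match weights order", call. = FALSE)
  if (n < 2) stop("local Moran's I needs at least 2 areas", call. = FALSE)
  z <- x - mean(x)
  m2 <- sum(z^2) / n
  if (m2 == 0)
    stop("'x' is constant: local Moran's I undefined (zero variance)", call. = FALSE)
  li <- (z / m2) * drop(w %*% z)
  names(li) <- weights_ids(weights, n)
  li
}

#' LISA cluster and outlier classification
#'
#' Runs a conditional permutation test per area (the area's own value is
#' held fixed while the remaining values are permuted among the other
#' areas), optionally applies a Bonferroni correction over the n areas
#' tested, and labels each significant area by the quadrant of its
#' mean-centered value and mean-centered spatial lag:
#' `HH` (high value, high lag), `LL`, `HL` (high-low outlier), `LH`;
#' non-significant areas are `NS`.  P-values are two-sided (folded around
#' the permutation mean) so both cluster and outlier types are detectable.
#'
#' @inheritParams moran_mc_test
#' @param alpha significance level (default 0.05).
#' @param bonferroni divide the threshold by n (equivalently multiply
#'   p-values by n), default `TRUE`.
#' @return data frame of class `"lisa_result"` with columns `area_id`,
#'   `local_i`, `p_value`, `p_adjusted`, `cluster`; attributes `alpha`,
#'   `threshold` (per-area level actually applied), `nperm`, `alternative`.
#' @export
lisa_classify <- function(x, weights, nperm = 999, alpha = 0.05,
                          bonferroni = TRUE, seed = NULL) {
  w <- weights_matrix(weights)
  n <- length(x)
  if (nperm < 19) stop("'nperm' must be at least 19", call. = FALSE)
  z <- x - mean(x)
  m2 <- sum(z^2) / n
  if (m2 == 0)
    stop("'x' is constant: local Moran's I undefined (zero variance)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  li <- local_moran(x, w)
  lag <- drop(w %*% z)

  p <- rep(1, n)
  for (i in seq_len(n)) {
    nbw <- w[i, -i]
    nz <- which(nbw != 0)
    if (length(nz) == 0) { p[i] <- 1; next }
    zi_others <- z[-i]
    d <- length(nz)
    # conditional permutation: draw d values without replacement from z[-i]
    idx <- vapply(seq_len(nperm), function(k) sample.int(n - 1L, d), integer(d))
    simlag <- crossprod(matrix(zi_others[idx], nrow = d), nbw[nz])
    sim <- (z[i] / m2) * drop(simlag)
    ctr <- mean(sim)
    m <- sum(abs(sim - ctr) >= abs(li[i] - ctr))
    p[i] <- (m + 1) / (nperm + 1)
  }

  p_adj <- if (bonferroni) pmin(1, p * n) else p
  threshold <- if (bonferroni) alpha / n else alpha
  sig <- p_adj <= alpha & z != 0 & lag != 0
  cluster <- rep("NS", n)
  cluster[sig & z > 0 & lag > 0] <- "HH"
  cluster[sig & z < 0 & lag < 0] <- "LL"
  cluster[sig & z > 0 & lag < 0] <- "HL"
  cluster[sig & z < 0 & lag > 0] <- "LH"

  out <- data.frame(area_id = weights_ids(weights, n),
                    local_i = as.numeric(li), p_value = p, p_adjusted = p_adj,
                    cluster = cluster, stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  attr(out, "threshold") <- threshold
  attr(out, "nperm") <- nperm
  attr(out, "alternative") <- "two-sided (folded), conditional permutation"
  class(out) <- c("lisa_result", "data.frame")
  out
}
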