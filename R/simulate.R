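#' Generator settings for the synthetic areal study
#'
#' Defaults emulate a province-wide areal asthma study design: ~144 areas
#' (a 12 x 12 grid standing in for 141 irregular health-planning units) with
#' mean area population 12,901 split over 2 sexes x 3 age bands, an ordinal
#' 1-6 rurality classification with urban areas (level 1) most frequent, and
#' spatially smooth continuous covariates confined to realistic observed
#' ranges: a standardized material-deprivation score, relative humidity (%),
#' maximum temperature (degrees C), family physicians per 10,000, NO2 (ppb)
#' and total pollen (particles/m3).
#'
#' @param mean_population mean total population per area.
#' @param population_cv coefficient of variation of area totals.
#' @param strata stratum labels (age band x sex).
#' @param stratum_shares population share per stratum (sums to 1).
#' @param stratum_rates baseline outcome rate per stratum used for expected
#'   counts; defaults rise from childhood into adulthood.
#' @param covariate_ranges named list of `c(min, median, max)` triples the
#'   continuous covariates are confined to.
#' @param rurality_cum cumulative probabilities of rurality levels 1..6
#'   (last entry 1); defaults put the median at level 2 and the upper
#'   quartile at level 3.
#' @param covariate_rho,spatial_share CAR mixing of the latent covariate
#'   fields and the share of covariate variance that is spatially
#'   structured (the rest is independent noise).
#' @return list of class `"study_config"`.
#' @export
study_config <- function(
    mean_population = 12901,
    population_cv = 0.25,
    strata = c("child:F", "child:M", "adult:F", "adult:M",
               "senior:F", "senior:M"),
    stratum_shares = c(0.10, 0.10, 0.30, 0.30, 0.10, 0.10),
    stratum_rates = c("child:F" = 0.022, "child:M" = 0.028,
                      "adult:F" = 0.046, "adult:M" = 0.038,
                      "senior:F" = 0.052, "senior:M" = 0.044),
    covariate_ranges = list(
      deprivation = c(-1.15, -0.20, 1.46),
      rh          = c(56.02, 66.07, 69.56),
      max_temp    = c(34.62, 36.69, 37.93),
      physicians  = c(0, 8.62, 51.08),
      no2         = c(3.64, 8.71, 24.84),
      pollen      = c(118.14, 140.42, 161.27)),
    rurality_cum = c(0.40, 0.55, 0.80, 0.90, 0.96, 1.00),
    covariate_rho = 0.75,
    spatial_share = 0.5) {
  if (length(strata) == 0) stop("'strata' must be non-empty", call. = FALSE)
  if (length(stratum_shares) != length(strata) ||
      abs(sum(stratum_shares) - 1) > 1e-8)
    stop("'stratum_shares' must match 'strata' and sum to 1", call. = FALSE)
  if (!all(strata %in% names(stratum_rates)))
    stop("every stratum needs a baseline rate", call. = FALSE)
  if (length(rurality_cum) != 6 || is.unsorted(rurality_cum) ||
      abs(rurality_cum[6] - 1) > 1e-8)
    stop("'rurality_cum' must be 6 nondecreasing values ending in 1", call. = FALSE)
  structure(as.list(environment()), class = "study_config")
}

#' Simulate stratified populations and covariates on a lattice
#'
#' Area totals are drawn from a gamma distribution around the configured
#' mean and split over the configured strata (with mild area-level noise in
#' the shares).  Each continuous covariate is a monotone transform of a
#' latent field mixing a Leroux-CAR-correlated component with independent
#' noise, rescaled so its median matches the configured target and clipped
#' into the configured `[min, max]` range (clipping keeps the draw
#' deterministic).  Ordinal rurality is produced by thresholding a smooth
#' latent field at the configured cumulative proportions, making level 1
#' (urban) the most frequent and reproducing the urban-clustered pattern.
#'
#' @param lattice an `"area_lattice"`.
#' @param config a [study_config()].
#' @param seed integer seed; output is deterministic given it.
#' @return list with
#'   \describe{
#'     \item{population}{data frame `area_id`, `stratum`, `population`}
#'     \item{covariates}{data frame `area_id`, `rurality` (ordinal 1-6) and
#'       one column per configured continuous covariate}
#'   }
#' @export
simulate_population_and_covariates <- function(lattice, config = study_config(),
                                               seed = 1L) {
  stopifnot(inherits(lattice, "area_lattice"))
  if (!inherits(config, "study_config")) stop("'config' must be a study_config",
                                              call. = FALSE)
  if (length(config$strata) == 0) stop("'strata' must be non-empty", call. = FALSE)
  set.seed(seed)
  n <- length(lattice$area_id)
  w <- lattice_weights(lattice)

  # area totals: gamma around the configured mean
  cv <- config$population_cv
  shape <- 1 / cv^2
  totals <- stats::rgamma(n, shape = shape, rate = shape / config$mean_population)
  totals <- pmax(round(totals), length(config$strata))

  shares <- config$stratum_shares
  k <- length(shares)
  noise <- matrix(stats::rnorm(n * k, 0, 0.05), n, k)
  sh <- pmax(matrix(shares, n, k, byrow = TRUE) * exp(noise), 1e-6)
  sh <- sh / rowSums(sh)
  pops <- round(sh * totals)

  population <- data.frame(
    area_id = rep(lattice$area_id, each = k),
    stratum = rep(config$strata, times = n),
    population = as.vector(t(pops)),
    stringsAsFactors = FALSE)

  smooth_field <- function() {
    f <- sample_leroux_effects(w, rho = config$covariate_rho, tau2 = 1)
    e <- stats::rnorm(n)
    z <- sqrt(config$spatial_share) * f / stats::sd(f) +
         sqrt(1 - config$spatial_share) * e
    (z - mean(z)) / stats::sd(z)
  }

  covs <- data.frame(area_id = lattice$area_id, stringsAsFactors = FALSE)

  # ordinal rurality by thresholding a smooth latent field at the configured
  # cumulative proportions (empirical quantiles: deterministic level counts)
  latent <- smooth_field()
  cuts <- stats::quantile(latent, config$rurality_cum[-6])
  covs$rurality <- as.integer(1 + findInterval(latent, cuts, left.open = TRUE))

  for (nm in names(config$covariate_ranges)) {
    rng <- config$covariate_ranges[[nm]]
    lo <- rng[1]; md <- rng[2]; hi <- rng[3]
    z <- smooth_field()
    # centre on the target median, spread ~ quarter of the range per sd
    x <- md + z * (hi - lo) / 4
    covs[[nm]] <- pmin(pmax(x, lo), hi)
  }

  list(population = population, covariates = covs)
}

#' Ground truth of a synthetic study
#'
#' Records the generating parameters alongside every simulated dataset so
#' downstream recovery can be scored.
#'
#' @param beta named numeric log-relative-risks (including intercept first).
#' @param rho spatial mixing in `[0, 1]`.
#' @param tau2 positive spatial variance scale.
#' @param phi per-area spatial effects.
#' @param seed integer seed the counts were generated with.
#' @return list of class `"synthetic_truth"`.
#' @export
synthetic_truth <- function(beta, rho, tau2, phi, seed) {
  if (rho < 0 || rho > 1) stop("'rho' must lie in [0, 1]", call. = FALSE)
  if (tau2 <= 0) stop("'tau2' must be positive", call. = FALSE)
  structure(list(beta = beta, rho = rho, tau2 = tau2, phi = phi,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' Simulate observed counts from the Poisson areal model
#'
#' Draws `y_i ~ Poisson(E_i * exp(x_i' beta + phi_i))` for given expected
#' counts, a centered design and a [synthetic_truth()] (whose `seed` makes
#' the counts reproducible).  Intercept handling: if `truth$beta` has one
#' more element than `design` has columns, its first element is the
#' intercept.
#'
#' @param expected non-negative expected counts `E_i`.
#' @param design numeric matrix of centered covariates (n rows; may have
#'   zero columns).
#' @param truth a [synthetic_truth()] with `phi` of length n.
#' @return integer vector of counts.
#' @export
simulate_counts <- function(expected, design, truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (any(expected < 0) || anyNA(expected))
    stop("expected counts must be non-negative", call. = FALSE)
  design <- as.matrix(design)
  n <- length(expected)
  if (nrow(design) != n || length(truth$phi) != n)
    stop("design rows and phi length must match 'expected'", call. = FALSE)
  beta <- truth$beta
  intercept <- 0
  if (length(beta) == ncol(design) + 1L) {
    intercept <- beta[1]
    beta <- beta[-1]
  } else if (length(beta) != ncol(design))
    stop("length of truth$beta does not match the design", call. = FALSE)
  eta <- intercept + (if (ncol(design)) drop(design %*% beta) else 0) + truth$phi
  set.seed(truth$seed)
  stats::rpois(n, expected * exp(eta))
}

#' Simulate a complete synthetic areal study with known truth
#'
#' One call producing everything the downstream chain needs: lattice,
#' symmetric contiguity weights, stratified population, Table-like
#' covariates, expected counts from the configured stratum rates, the model
#' covariates `x1` (standardized deprivation) and `x2` (standardized NO2),
#' a Leroux CAR spatial-effect draw and Poisson counts.  Defaults define the
#' package's reference recovery study: a 12 x 12 grid (144 areas,
#' approximating a 141-unit geography), `beta = (0.5, -0.3)` on the two
#' standardized covariates, `rho = 0.5`, `tau2 = 0.05`, and mean expected
#' counts around 500.
#'
#' @param seed integer master seed (sub-seeds for covariates, spatial
#'   effects and counts are derived from it).
#' @param nrows,ncols grid dimensions.
#' @param beta length-2 true log-relative-risks for `x1`, `x2`.
#' @param intercept true intercept (log baseline relative risk).
#' @param rho,tau2 true spatial parameters of the Leroux effect.
#' @param config a [study_config()].
#' @return list of class `"synthetic_study"`: `area_table` (area_id,
#'   observed, expected, covariates, x1, x2), `population`, `lattice`,
#'   `weights` (symmetric binary), `truth` (a [synthetic_truth()]),
#'   `rates` (stratum rates used).
#' @export
simulate_study <- function(seed = 1L, nrows = 12, ncols = 12,
                           beta = c(x1 = 0.5, x2 = -0.3), intercept = 0,
                           rho = 0.5, tau2 = 0.05,
                           config = study_config()) {
  lattice <- make_grid_lattice(nrows, ncols)
  weights <- lattice_weights(lattice)
  sub <- derive_seeds(seed, 3)

  pc <- simulate_population_and_covariates(lattice, config, seed = sub[1])
  rates <- data.frame(stratum = config$strata,
                      rate = unname(config$stratum_rates[config$strata]),
                      stringsAsFactors = FALSE)
  expected <- compute_expected_counts(pc$population, rates)

  x1 <- drop(scale(pc$covariates$deprivation))
  x2 <- drop(scale(pc$covariates$no2))
  phi <- sample_leroux_effects(weights, rho = rho, tau2 = tau2, seed = sub[2])
  truth <- synthetic_truth(beta = c(`(Intercept)` = unname(intercept),
                                    x1 = unname(beta[1]), x2 = unname(beta[2])),
                           rho = rho, tau2 = tau2, phi = phi, seed = sub[3])
  observed <- simulate_counts(expected, cbind(x1 = x1, x2 = x2), truth)

  area_table <- data.frame(pc$covariates,
                           x1 = x1, x2 = x2,
                           expected = as.numeric(expected),
                           observed = observed,
                           stringsAsFactors = FALSE)
  structure(list(area_table = area_table, population = pc$population,
                 lattice = lattice, weights = weights, truth = truth,
                 rates = rates, seed = as.integer(seed)),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic areal study:", nrow(x$area_table), "areas, seed", x$seed, "\n")
  cat(sprintf("  truth: beta = (%s), rho = %.2f, tau2 = %.3f\n",
              paste(signif(x$truth$beta, 3), collapse = ", "),
              x$truth$rho, x$truth$tau2))
  invisible(x)
}

# Derive k reproducible 31-bit sub-seeds from one master seed.
derive_seeds <- function(seed, k) {
  (as.numeric(seed) * 1009 + 7 * seq_len(k)) %% 2147483647
}

#' Write a synthetic study to disk
#'
#' Serializes the area table and stratified population as CSV, the lattice
#' as a GAL neighbour file plus centroid CSV, and the ground truth as a JSON
#' sidecar.
#'
#' @param study a `"synthetic_study"`.
#' @param dir output directory (created if missing).
#' @return named character vector of the files written, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c(
    area_table = file.path(dir, "area_table.csv"),
    population = file.path(dir, "population.csv"),
    centroids = file.path(dir, "centroids.csv"),
    gal = file.path(dir, "lattice.gal"),
    truth = file.path(dir, "truth.json"))
  utils::write.csv(study$area_table, files["area_table"], row.names = FALSE)
  utils::write.csv(study$population, files["population"], row.names = FALSE)
  utils::write.csv(data.frame(area_id = study$lattice$area_id,
                              study$lattice$centroids),
                   files["centroids"], row.names = FALSE)
  write_gal(study$weights, files["gal"])
  truth <- study$truth
  jsonlite::write_json(
    list(beta = as.list(truth$beta), rho = truth$rho, tau2 = truth$tau2,
         phi = unname(truth$phi), seed = truth$seed),
    files["truth"], auto_unbox = TRUE, digits = NA)
  invisible(files)
}
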