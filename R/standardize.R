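#' Expected counts by indirect age-sex standardization
#'
#' Indirect standardization applies standard stratum-specific rates to each
#' area's stratified population: `E_i = sum_s n_is * r_s`.  With an
#' *internal* standard (rates computed from the pooled study population,
#' see [internal_standard_rates()]) the expected counts reproduce the
#' observed total exactly, so the whole-region SMR is 1.
#'
#' @param population data frame with columns `area_id`, `stratum`,
#'   `population` (one row per area-stratum pair, populations >= 0).
#' @param standard_rates data frame with columns `stratum`, `rate`
#'   (rates >= 0, one per stratum appearing in `population`).
#' @return named numeric vector of expected counts `E_i`, in order of first
#'   appearance of each area in `population`.
#' @seealso [compute_smr()], [internal_standard_rates()]
#' @export
compute_expected_counts <- function(population, standard_rates) {
  check_population(population)
  if (!all(c("stratum", "rate") %in% names(standard_rates)))
    stop("'standard_rates' needs columns 'stratum' and 'rate'", call. = FALSE)
  if (any(standard_rates$rate < 0) || anyNA(standard_rates$rate))
    stop("standard rates must be non-negative", call. = FALSE)
  r <- standard_rates$rate[match(population$stratum, standard_rates$stratum)]
  if (anyNA(r)) {
    missing <- setdiff(unique(population$stratum), standard_rates$stratum)
    stop("no standard rate for stratum/strata: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  areas <- unique(as.character(population$area_id))
  e <- vapply(
    split(population$population * r, factor(population$area_id, levels = areas)),
    sum, numeric(1)
  )
  e[areas]
}

#' Internal standard rates from the pooled study population
#'
#' Computes per-stratum rates `r_s = sum_i O_is / sum_i n_is` from the study
#' data itself, the "internal standard" convention under which indirect
#' standardization satisfies `sum(E) == sum(O)` identically.
#'
#' @param population as in [compute_expected_counts()].
#' @param observed data frame with columns `area_id`, `stratum`, `count`.
#' @return data frame with columns `stratum`, `rate`.
#' @export
internal_standard_rates <- function(population, observed) {
  check_population(population)
  if (!all(c("stratum", "count") %in% names(observed)))
    stop("'observed' needs columns 'stratum' and 'count'", call. = FALSE)
  n_s <- tapply(population$population, population$stratum, sum)
  o_s <- tapply(observed$count, observed$stratum, sum)
  strata <- names(n_s)
  if (!all(strata %in% names(o_s)))
    stop("'observed' is missing strata present in 'population'", call. = FALSE)
  if (any(n_s == 0 & o_s[strata] > 0))
    stop("stratum with zero population but positive counts", call. = FALSE)
  rate <- ifelse(n_s > 0, o_s[strata] / n_s, 0)
  data.frame(stratum = strata, rate = as.numeric(rate),
             row.names = NULL, stringsAsFactors = FALSE)
}

check_population <- function(population) {
  req <- c("area_id", "stratum", "population")
  if (!all(req %in% names(population)))
    stop("'population' needs columns area_id, stratum, population", call. = FALSE)
  if (nrow(population) == 0 || length(unique(population$stratum)) == 0)
    stop("'population' must contain at least one stratum", call. = FALSE)
  if (any(population$population < 0) || anyNA(population$population))
    stop("populations must be non-negative", call. = FALSE)
  key <- paste(population$area_id, population$stratum)
  if (anyDuplicated(key))
    stop("duplicate (area, stratum) rows in 'population'", call. = FALSE)
  invisible(TRUE)
}

#' Standardized morbidity ratios
#'
#' `SMR_i = O_i / E_i`.  Areas with `E_i = 0` and `O_i = 0` get a missing
#' SMR and are flagged rather than silently dropped; `E_i = 0` with
#' `O_i > 0` is an error (the SMR is undefined).
#'
#' @param observed integer observed counts `O_i`.
#' @param expected expected counts `E_i >= 0` (same length and order).
#' @param area_id optional identifiers; defaults to names of `expected`.
#' @param denominator_kind `"total-population"` for prevalence-type
#'   outcomes or `"prevalent-population"` for health-service outcomes whose
#'   denominator is the prevalent pool.
#' @return data frame of class `"outcome_table"` with columns `area_id`,
#'   `observed`, `expected`, `smr`, `undefined` and attribute
#'   `denominator_kind`.
#' @export
compute_smr <- function(observed, expected, area_id = NULL,
                        denominator_kind = c("total-population",
                                             "prevalent-population")) {
  denominator_kind <- match.arg(denominator_kind)
  if (length(observed) != length(expected))
    stop("'observed' and 'expected' lengths differ", call. = FALSE)
  if (any(expected < 0) || anyNA(expected))
    stop("expected counts must be non-negative", call. = FALSE)
  if (any(observed < 0) || anyNA(observed))
    stop("observed counts must be non-negative", call. = FALSE)
  bad <- expected == 0 & observed > 0
  if (any(bad))
    stop("SMR undefined: zero expected count with positive observed count ",
         "in area(s) ", paste(which(bad), collapse = ", "), call. = FALSE)
  if (is.null(area_id)) area_id <- names(expected)
  if (is.null(area_id)) area_id <- sprintf("A%03d", seq_along(expected))
  undefined <- expected == 0
  smr <- ifelse(undefined, NA_real_, observed / expected)
  out <- data.frame(area_id = as.character(area_id),
                    observed = as.numeric(observed),
                    expected = as.numeric(expected),
                    smr = smr, undefined = undefined,
                    stringsAsFactors = FALSE)
  attr(out, "denominator_kind") <- denominator_kind
  class(out) <- c("outcome_table", "data.frame")
  out
}

#' Multi-year pooled outcome rate
#'
#' Averages annual rates over a study period (the mean of `count_y /
#' denom_y`), reported per `per` population (default per 1,000).  Averaging
#' annual rates damps random year-to-year fluctuation; the alternative
#' convention, the rate of pooled counts `sum(count) / sum(denom)`, is
#' available via `method = "pooled-counts"`.
#'
#' @param yearly_counts,yearly_denominators equal-length numeric vectors of
#'   per-year counts and denominators (denominators > 0).
#' @param per reporting scale (default 1000).
#' @param method `"mean-of-rates"` (default) or `"pooled-counts"`.
#' @return single pooled rate per `per` population.
#' @export
pooled_period_rate <- function(yearly_counts, yearly_denominators,
                               per = 1000,
                               method = c("mean-of-rates", "pooled-counts")) {
  method <- match.arg(method)
  if (length(yearly_counts) != length(yearly_denominators))
    stop("count and denominator series must cover the same years", call. = FALSE)
  if (length(yearly_counts) == 0)
    stop("empty series", call. = FALSE)
  if (any(yearly_denominators <= 0) || anyNA(yearly_denominators))
    stop("denominators must be positive in every year", call. = FALSE)
  rate <- switch(method,
    "mean-of-rates" = mean(yearly_counts / yearly_denominators),
    "pooled-counts" = sum(yearly_counts) / sum(yearly_denominators)
  )
  rate * per
}
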