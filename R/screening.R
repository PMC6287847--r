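#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from regressing column `j`
#' on all other columns (with intercept).  Exactly collinear columns are
#' reported as `Inf` rather than raising an error, so step-wise deletion can
#' act on them.
#'
#' @param design numeric matrix or data frame of covariate columns
#'   (at least 2 columns, none constant).
#' @return named numeric vector of VIFs (`>= 1`, `Inf` flags exact
#'   collinearity).
#' @export
vif <- function(design) {
  x <- as.matrix(design)
  if (!is.numeric(x)) stop("'design' must be numeric", call. = FALSE)
  p <- ncol(x)
  if (p < 2) stop("VIF needs at least two columns", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(p))
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("constant column(s): ", paste(colnames(x)[sds == 0], collapse = ", "),
         call. = FALSE)
  out <- vapply(seq_len(p), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((x[, j] - mean(x[, j]))^2)
    r2 <- 1 - rss / tss
    if (1 - r2 < 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(x)
  out
}

#' Step-wise VIF deletion
#'
#' Repeatedly computes VIFs and removes the single column with the highest
#' VIF while the maximum exceeds `threshold`; ties are broken by column
#' order.  The full deletion trace (VIFs at each step, column removed) is
#' returned so the screening can be audited and replayed.
#'
#' @inheritParams vif
#' @param threshold VIF cut-off above which deletion continues
#'   (default 10, the conventional rule of thumb; must exceed 1).
#' @return list of class `"vif_trace"`:
#'   \describe{
#'     \item{retained}{column names kept}
#'     \item{deleted}{column names removed, in deletion order}
#'     \item{trace}{list of per-step named VIF vectors (computed before each
#'       deletion; the final entry has max VIF <= threshold)}
#'   }
#' @export
vif_stepwise <- function(design, threshold = 10) {
  if (threshold <= 1) stop("'threshold' must exceed 1", call. = FALSE)
  x <- as.matrix(design)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  deleted <- character(0)
  trace <- list()
  repeat {
    if (ncol(x) < 2) {
      if (ncol(x) == 0)
        stop("all columns deleted: degenerate design", call. = FALSE)
      break  # a single remaining column has no multicollinearity
    }
    v <- vif(x)
    trace[[length(trace) + 1L]] <- v
    if (max(v) <= threshold) break
    drop_j <- which.max(v)  # which.max takes the first maximum: column-order tie-break
    deleted <- c(deleted, colnames(x)[drop_j])
    x <- x[, -drop_j, drop = FALSE]
  }
  structure(list(retained = colnames(x), deleted = deleted, trace = trace,
                 threshold = threshold),
            class = "vif_trace")
}

#' @export
print.vif_trace <- function(x, ...) {
  cat("Step-wise VIF screening (threshold ", x$threshold, ")\n", sep = "")
  cat("  deleted:", if (length(x$deleted)) paste(x$deleted, collapse = " > ")
                    else "(none)", "\n")
  cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  invisible(x)
}

#' Deviation-from-the-mean centering
#'
#' Centers continuous covariate columns on their means (the
#' deviation-from-the-mean transformation that makes an intercept
#' interpretable as the risk at average covariate values).  Non-numeric and
#' explicitly excluded columns are untouched.  The centering constants are
#' stored in the `"centers"` attribute for back-transformation.
#'
#' @param data data frame.
#' @param cols columns to center; default all numeric columns except `skip`.
#' @param skip column names never centered (ids, counts, ordinal codes).
#' @return `data` with the selected columns centered and attribute
#'   `centers` (named vector of subtracted means).
#' @export
center_covariates <- function(data, cols = NULL,
                              skip = c("area_id", "observed", "expected")) {
  if (is.null(cols)) {
    num <- vapply(data, is.numeric, logical(1))
    cols <- setdiff(names(data)[num], skip)
  }
  centers <- vapply(cols, function(cl) mean(data[[cl]]), numeric(1))
  for (cl in cols) data[[cl]] <- data[[cl]] - centers[[cl]]
  attr(data, "centers") <- centers
  data
}

#' Correlation screening report
#'
#' Pairwise correlation of candidate covariates with each other and with an
#' outcome, as a reporting aid before model fitting.  No automatic deletion
#' is applied.
#'
#' @param design numeric data frame/matrix of covariates.
#' @param outcome optional numeric outcome vector.
#' @param method correlation type passed to [stats::cor()].
#' @return list with `covariate_cor` (matrix) and, when `outcome` is given,
#'   `outcome_cor` (named vector).
#' @export
correlation_screen <- function(design, outcome = NULL, method = "pearson") {
  x <- as.matrix(design)
  out <- list(covariate_cor = stats::cor(x, method = method))
  if (!is.null(outcome))
    out$outcome_cor <- drop(stats::cor(x, outcome, method = method))
  out
}
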