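#' Spatial weights objects
#'
#' A `spatial_weights` object holds the n x n non-negative weight matrix
#' `w` that the exploratory spatial statistics and the CAR prior consume,
#' together with the fixed area ordering, the weighting style and a
#' symmetry flag.  Styles are `"binary"` (entries 0/1) and
#' `"row-standardized"` (each non-island row sums to 1).
#'
#' @param w numeric matrix with zero diagonal and non-negative entries.
#' @param area_id character identifiers in matrix order; defaults to
#'   `rownames(w)` or `"A001"...`.
#' @param style `"binary"` or `"row-standardized"`.
#' @return an object of class `"spatial_weights"`.
#' @export
spatial_weights <- function(w, area_id = NULL,
                            style = c("binary", "row-standardized")) {
  style <- match.arg(style)
  w <- as.matrix(w)
  n <- nrow(w)
  if (ncol(w) != n) stop("'w' must be square", call. = FALSE)
  if (any(diag(w) != 0)) stop("weights must have a zero diagonal", call. = FALSE)
  if (any(w < 0)) stop("weights must be non-negative", call. = FALSE)
  if (style == "binary" && !all(w %in% c(0, 1)))
    stop("binary style requires 0/1 entries", call. = FALSE)
  if (style == "row-standardized") {
    rs <- rowSums(w)
    bad <- rs > 0 & abs(rs - 1) > 1e-12
    if (any(bad)) stop("row-standardized style requires non-island row sums of 1",
                       call. = FALSE)
  }
  if (is.null(area_id)) area_id <- rownames(w)
  if (is.null(area_id)) area_id <- sprintf("A%03d", seq_len(n))
  area_id <- as.character(area_id)
  if (length(area_id) != n) stop("'area_id' length must match 'w'", call. = FALSE)
  dimnames(w) <- list(area_id, area_id)
  structure(
    list(w = w, area_id = area_id, style = style,
         symmetric = isSymmetric(unname(w))),
    class = "spatial_weights"
  )
}

#' @export
print.spatial_weights <- function(x, ...) {
  isl <- sum(rowSums(x$w) == 0)
  cat("Spatial weights:", length(x$area_id), "areas, style:", x$style,
      if (x$symmetric) "(symmetric)" else "(asymmetric)", "\n")
  cat("  links:", sum(x$w > 0), " islands:", isl, "\n")
  invisible(x)
}

# Accept a spatial_weights object or a raw matrix in internal code.
weights_matrix <- function(weights) {
  if (inherits(weights, "spatial_weights")) weights$w
  else if (is.matrix(weights)) {
    if (any(diag(weights) != 0)) stop("weights must have a zero diagonal", call. = FALSE)
    weights
  } else stop("'weights' must be a spatial_weights object or matrix", call. = FALSE)
}

weights_ids <- function(weights, n) {
  if (inherits(weights, "spatial_weights")) weights$area_id
  else if (!is.null(rownames(weights))) rownames(weights)
  else sprintf("A%03d", seq_len(n))
}

#' Binary contiguity weights from a lattice
#'
#' @param lattice an `"area_lattice"`.
#' @return symmetric binary `spatial_weights`.
#' @export
lattice_weights <- function(lattice) {
  spatial_weights(lattice_adjacency(lattice), lattice$area_id, "binary")
}

#' k-nearest-neighbour spatial weights
#'
#' Builds binary weights in which `w[i, j] = 1` iff `j` is among the `k`
#' nearest areas to `i` by Euclidean distance on planar coordinates.
#' k-NN neighbourhoods are generally asymmetric; use [symmetrize()] before
#' passing them to a CAR model.  Distance ties are broken by ascending
#' position in the `area_id` ordering, so results are reproducible on
#' exactly regular geometries.
#'
#' @param centroids n x 2 matrix or data frame of planar (x, y) coordinates;
#'   a 3-column data frame is taken as (area_id, x, y).
#' @param k number of neighbours, `1 <= k <= n - 1`.
#' @param area_id optional identifiers; defaults to rownames or the first
#'   column of a 3-column data frame.
#' @return binary `spatial_weights` with every row summing to `k`.
#' @export
knn_weights <- function(centroids, k, area_id = NULL) {
  if (is.data.frame(centroids) && ncol(centroids) >= 3) {
    if (is.null(area_id)) area_id <- as.character(centroids[[1]])
    xy <- as.matrix(centroids[, 2:3])
  } else {
    xy <- as.matrix(centroids)
    if (is.null(area_id)) area_id <- rownames(xy)
  }
  storage.mode(xy) <- "double"
  n <- nrow(xy)
  if (is.null(area_id)) area_id <- sprintf("A%03d", seq_len(n))
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    stop("'k' must be a positive integer", call. = FALSE)
  if (k >= n)
    stop("'k' must be smaller than the number of areas", call. = FALSE)

  w <- matrix(0, n, n)
  d2 <- as.matrix(stats::dist(xy))^2
  for (i in seq_len(n)) {
    di <- d2[i, ]
    di[i] <- Inf
    # order(distance, index): ties broken by ascending area_id position
    nb <- order(di, seq_len(n))[seq_len(k)]
    w[i, nb] <- 1
  }
  spatial_weights(w, area_id, "binary")
}

#' Symmetrize binary weights
#'
#' Applies the "either-neighbour" rule `w'[i, j] = max(w[i, j], w[j, i])`,
#' turning (possibly asymmetric) k-NN weights into the symmetric adjacency
#' a CAR prior requires.
#'
#' @param weights binary `spatial_weights`.
#' @return symmetric binary `spatial_weights`.
#' @export
symmetrize <- function(weights) {
  stopifnot(inherits(weights, "spatial_weights"))
  if (weights$style != "binary")
    stop("symmetrize() expects binary weights", call. = FALSE)
  w <- pmax(weights$w, t(weights$w))
  spatial_weights(w, weights$area_id, "binary")
}

#' Row-standardize spatial weights
#'
#' Divides every non-island row by its sum so rows sum to 1.  Island rows
#' (no neighbours) are left all-zero and reported with a warning.
#' Idempotent.
#'
#' @param weights `spatial_weights` with non-negative entries.
#' @return `spatial_weights` with style `"row-standardized"`.
#' @export
row_standardize <- function(weights) {
  stopifnot(inherits(weights, "spatial_weights"))
  w <- weights$w
  rs <- rowSums(w)
  islands <- rs == 0
  if (any(islands))
    warning(sum(islands), " island area(s) left with all-zero weights: ",
            paste(weights$area_id[islands], collapse = ", "), call. = FALSE)
  w[!islands, ] <- w[!islands, , drop = FALSE] / rs[!islands]
  spatial_weights(w, weights$area_id, "row-standardized")
}

#' Read and write GAL neighbour-list files
#'
#' GAL is the plain-text neighbour-list format used by GeoDa-family tools:
#' a header line `0 n <name> <id-variable>` followed, for each area, by a
#' line `<id> <degree>` and a line listing its neighbours' ids.  Only the
#' binary neighbour structure is stored; weights are reconstructed as 0/1.
#'
#' @param weights binary `spatial_weights` to write.
#' @param path file path.
#' @param name,id_var header fields recorded in the file.
#' @return `write_gal()` returns `path` invisibly; `read_gal()` returns a
#'   binary `spatial_weights`.
#' @export
write_gal <- function(weights, path, name = "lattice", id_var = "area_id") {
  stopifnot(inherits(weights, "spatial_weights"))
  if (weights$style != "binary")
    stop("GAL files store binary neighbour lists", call. = FALSE)
  w <- weights$w
  ids <- weights$area_id
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("0", nrow(w), name, id_var), con)
  for (i in seq_len(nrow(w))) {
    nb <- which(w[i, ] > 0)
    writeLines(paste(ids[i], length(nb)), con)
    writeLines(paste(ids[nb], collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_gal
#' @export
read_gal <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n <- as.integer(hdr[2])
  ids <- character(n)
  nb_ids <- vector("list", n)
  pos <- 2L
  for (i in seq_len(n)) {
    rec <- strsplit(trimws(lines[pos]), "\\s+")[[1]]
    ids[i] <- rec[1]
    deg <- as.integer(rec[2])
    nb_ids[[i]] <- if (deg > 0) strsplit(trimws(lines[pos + 1L]), "\\s+")[[1]]
                   else character(0)
    pos <- pos + 2L
  }
  w <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    j <- match(nb_ids[[i]], ids)
    if (anyNA(j)) stop("GAL file references unknown area id", call. = FALSE)
    w[i, j] <- 1
  }
  spatial_weights(w, ids, "binary")
}
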