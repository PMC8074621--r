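# Spatial weights: queen contiguity, k-nearest-neighbour, same-district.
# Weights are binary and stored sparsely as an edge list of unit indices.

new_spatial_weights <- function(ids, edges, scheme, symmetric, k = NULL) {
  structure(list(ids = ids, edges = edges, scheme = scheme,
                 symmetric = symmetric, k = k, n = length(ids)),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("spatial_weights: %d units, scheme '%s', %d directed links\n",
              x$n, x$scheme, nrow(x$edges)))
  invisible(x)
}

#' Sparse weights matrix
#'
#' @param w A "spatial_weights" object.
#' @return A sparse binary n x n [Matrix::sparseMatrix()].
#' @export
weights_matrix <- function(w) {
  Matrix::sparseMatrix(i = w$edges$from, j = w$edges$to, x = 1,
                       dims = c(w$n, w$n), dimnames = list(w$ids, w$ids))
}

#' Export weights as an edge-list table
#'
#' @param w A "spatial_weights" object.
#' @return data.frame(id_from, id_to).
#' @export
weights_edge_list <- function(w) {
  data.frame(id_from = w$ids[w$edges$from], id_to = w$ids[w$edges$to])
}

.warn_islands <- function(w) {
  deg <- tabulate(w$edges$from, nbins = w$n)
  if (any(deg == 0)) {
    warning("units with no neighbours: ", paste(w$ids[deg == 0], collapse = ", "))
  }
  w
}

#' Queen contiguity weights
#'
#' w = 1 when two polygons share at least one boundary point (edges or
#' corners); symmetric, zero diagonal.
#'
#' @param polygons List of vertex matrices.
#' @param ids Unit ids (defaults to names or indices).
#' @param tol Boundary-contact tolerance.
#' @return A "spatial_weights" object.
#' @export
queen_weights <- function(polygons, ids = NULL, tol = 1e-9) {
  m <- length(polygons)
  if (m < 2) stop("need at least 2 polygons")
  if (is.null(ids)) ids <- if (!is.null(names(polygons))) names(polygons) else as.character(seq_len(m))
  for (i in seq_len(m)) validate_polygon(polygons[[i]], ids[i])
  from <- integer(0); to <- integer(0)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      if (polygons_touch(polygons[[i]], polygons[[j]], tol)) {
        from <- c(from, i, j); to <- c(to, j, i)
      }
    }
  }
  .warn_islands(new_spatial_weights(ids, data.frame(from = from, to = to),
                                    "queen", symmetric = TRUE))
}

#' k-nearest-neighbour weights
#'
#' Each unit's k Euclidean-nearest other units are its neighbours
#' (asymmetry allowed); distance ties broken by smallest id.
#'
#' @param points n x 2 coordinate matrix.
#' @param k Number of neighbours (1 <= k < n).
#' @param ids Unit ids.
#' @return A "spatial_weights" object.
#' @export
knn_weights <- function(points, k, ids = NULL) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < number of points")
  if (is.null(ids)) ids <- as.character(seq_len(n))
  d <- as.matrix(stats::dist(points))
  diag(d) <- Inf
  from <- rep(seq_len(n), each = k)
  to <- integer(n * k)
  for (i in seq_len(n)) {
    ord <- order(d[i, ], seq_len(n))[seq_len(k)]
    to[((i - 1) * k + 1):(i * k)] <- ord
  }
  new_spatial_weights(ids, data.frame(from = from, to = to),
                      sprintf("knn(%d)", k), symmetric = FALSE, k = k)
}

#' Same-district weights
#'
#' All events in the same district are mutual neighbours (block-diagonal,
#' symmetric). Singleton districts yield zero rows with a warning.
#'
#' @param district_id Vector of district labels, one per event.
#' @param ids Unit ids.
#' @return A "spatial_weights" object.
#' @export
same_district_weights <- function(district_id, ids = NULL) {
  n <- length(district_id)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  groups <- split(seq_len(n), district_id)
  from <- integer(0); to <- integer(0)
  for (g in groups) {
    if (length(g) < 2) next
    pairs <- expand.grid(from = g, to = g)
    pairs <- pairs[pairs$from != pairs$to, ]
    from <- c(from, pairs$from); to <- c(to, pairs$to)
  }
  .warn_islands(new_spatial_weights(ids, data.frame(from = from, to = to),
                                    "same_district", symmetric = TRUE))
}
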