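# Planar polygon primitives used by the areal-aggregation and
# spatial-weights layers. Polygons are n x 2 numeric matrices of vertices
# in order (closing edge implicit), in a projected planar coordinate
# system; no CRS handling is done here.

#' Polygon area (shoelace formula)
#'
#' @param poly An n x 2 numeric matrix of vertices (unclosed ring).
#' @return Absolute area of the simple polygon.
#' @export
poly_area <- function(poly) {
  stopifnot(is.matrix(poly), ncol(poly) == 2, nrow(poly) >= 3)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Polygon centroid
#'
#' Area-weighted centroid of a simple polygon.
#' @param poly An n x 2 numeric matrix of vertices.
#' @return Numeric length-2 vector (x, y).
#' @export
poly_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(c(mean(x), mean(y)))
  c(sum((x + xn) * cr) / (6 * a), sum((y + yn) * cr) / (6 * a))
}

#' Point-in-polygon test
#'
#' Ray-casting test; points lying on the boundary (within `tol`) count as
#' inside, so events recorded exactly on a shared tract edge are claimed by
#' every touching tract and resolved by the caller's tie rule.
#'
#' @param px,py Point coordinates (vectors of equal length).
#' @param poly An n x 2 vertex matrix.
#' @param tol Distance tolerance for the boundary test.
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, poly, tol = 1e-12) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  out <- logical(length(px))
  for (i in seq_along(px)) {
    p <- px[i]; q <- py[i]
    # boundary check: distance from point to each edge
    dx <- xn - x; dy <- yn - y
    len2 <- dx^2 + dy^2
    t <- ifelse(len2 > 0, pmin(1, pmax(0, ((p - x) * dx + (q - y) * dy) / len2)), 0)
    d2 <- (x + t * dx - p)^2 + (y + t * dy - q)^2
    if (any(d2 <= tol^2)) { out[i] <- TRUE; next }
    inside <- FALSE
    for (e in seq_len(n)) {
      if ((y[e] > q) != (yn[e] > q)) {
        xint <- x[e] + (q - y[e]) / (yn[e] - y[e]) * (xn[e] - x[e])
        if (p < xint) inside <- !inside
      }
    }
    out[i] <- inside
  }
  out
}

is_convex <- function(poly, tol = 1e-12) {
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  pp <- rbind(poly, poly[1:2, , drop = FALSE])
  cr <- numeric(n)
  for (i in seq_len(n)) {
    v1 <- pp[i + 1, ] - pp[i, ]
    v2 <- pp[i + 2, ] - pp[i + 1, ]
    cr[i] <- v1[1] * v2[2] - v1[2] * v2[1]
  }
  all(cr >= -tol) || all(cr <= tol)
}

#' Clip a polygon against a convex polygon (Sutherland-Hodgman)
#'
#' Returns the vertices of `subject` intersected with convex `clip`.
#' The subject may be non-convex; the returned ring can then contain
#' zero-width bridges, whose shoelace area contribution is zero, so
#' [poly_area()] of the result is the true intersection area.
#'
#' @param subject,clip n x 2 vertex matrices; `clip` must be convex.
#' @return A vertex matrix (possibly with 0 rows for empty intersection).
#' @export
clip_polygon <- function(subject, clip) {
  if (!is_convex(clip)) stop("clip polygon must be convex")
  # ensure counter-clockwise clip orientation
  x <- clip[, 1]; y <- clip[, 2]
  if (sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) < 0) clip <- clip[nrow(clip):1, ]
  out <- subject
  nc <- nrow(clip)
  for (e in seq_len(nc)) {
    if (nrow(out) == 0) break
    a <- clip[e, ]; b <- clip[if (e == nc) 1 else e + 1, ]
    # signed distance to clip edge (positive = inside for CCW clip)
    side <- function(p) (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    inp <- out
    out <- matrix(numeric(0), ncol = 2)
    n <- nrow(inp)
    sv <- apply(inp, 1, side)
    for (i in seq_len(n)) {
      j <- if (i == n) 1 else i + 1
      si <- sv[i]; sj <- sv[j]
      if (si >= 0) out <- rbind(out, inp[i, ])
      if ((si > 0 && sj < 0) || (si < 0 && sj > 0)) {
        t <- si / (si - sj)
        out <- rbind(out, inp[i, ] + t * (inp[j, ] - inp[i, ]))
      }
    }
  }
  out
}

#' Intersection area of two simple polygons
#'
#' At least one of the two polygons must be convex (it is used as the
#' clipping window); rectangles and grid-block districts always qualify.
#'
#' @param p1,p2 Vertex matrices.
#' @return Nonnegative intersection area.
#' @export
poly_intersection_area <- function(p1, p2) {
  # cheap reject on bounding boxes
  if (max(p1[, 1]) < min(p2[, 1]) || max(p2[, 1]) < min(p1[, 1]) ||
      max(p1[, 2]) < min(p2[, 2]) || max(p2[, 2]) < min(p1[, 2])) return(0)
  if (is_convex(p2)) {
    res <- clip_polygon(p1, p2)
  } else if (is_convex(p1)) {
    res <- clip_polygon(p2, p1)
  } else {
    stop("poly_intersection_area: at least one polygon per pair must be convex")
  }
  if (nrow(res) < 3) return(0)
  poly_area(res)
}

# minimal distance between two segments (a1-a2, b1-b2)
.seg_dist <- function(a1, a2, b1, b2) {
  pt_seg <- function(p, s1, s2) {
    d <- s2 - s1
    l2 <- sum(d^2)
    t <- if (l2 > 0) max(0, min(1, sum((p - s1) * d) / l2)) else 0
    sqrt(sum((s1 + t * d - p)^2))
  }
  ccw <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  # proper intersection => distance zero
  d1 <- ccw(b1, b2, a1); d2 <- ccw(b1, b2, a2)
  d3 <- ccw(a1, a2, b1); d4 <- ccw(a1, a2, b2)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(0)
  min(pt_seg(a1, b1, b2), pt_seg(a2, b1, b2), pt_seg(b1, a1, a2), pt_seg(b2, a1, a2))
}

#' Do two polygon boundaries touch?
#'
#' TRUE when the boundaries come within `tol` of one another, i.e. the
#' polygons share at least one boundary point (edge or corner). Used for
#' queen contiguity.
#'
#' @param p1,p2 Vertex matrices.
#' @param tol Contact tolerance.
#' @return Logical scalar.
#' @export
polygons_touch <- function(p1, p2, tol = 1e-9) {
  if (max(p1[, 1]) < min(p2[, 1]) - tol || max(p2[, 1]) < min(p1[, 1]) - tol ||
      max(p1[, 2]) < min(p2[, 2]) - tol || max(p2[, 2]) < min(p1[, 2]) - tol) {
    return(FALSE)
  }
  n1 <- nrow(p1); n2 <- nrow(p2)
  for (i in seq_len(n1)) {
    a1 <- p1[i, ]; a2 <- p1[if (i == n1) 1 else i + 1, ]
    for (j in seq_len(n2)) {
      b1 <- p2[j, ]; b2 <- p2[if (j == n2) 1 else j + 1, ]
      if (.seg_dist(a1, a2, b1, b2) <= tol) return(TRUE)
    }
  }
  FALSE
}

rect_poly <- function(x0, y0, x1, y1) {
  matrix(c(x0, y0, x1, y0, x1, y1, x0, y1), ncol = 2, byrow = TRUE)
}

validate_polygon <- function(poly, id = "?") {
  if (!is.matrix(poly) || ncol(poly) != 2 || nrow(poly) < 3 ||
      any(!is.finite(poly))) {
    stop(sprintf("invalid polygon for unit '%s'", id))
  }
  if (poly_area(poly) <= 0) stop(sprintf("degenerate (zero-area) polygon for unit '%s'", id))
  invisible(TRUE)
}
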