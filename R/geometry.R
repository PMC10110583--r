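# Small planar-geometry primitives used by the spatial module. Polygons are
# data.frames with x/y vertex columns (implicitly closed, non-self-
# intersecting); coordinates are in micrometers throughout.

#' Area of a simple polygon
#'
#' Shoelace formula; vertex order does not matter (absolute value taken).
#'
#' @param poly data.frame with \code{x} and \code{y} vertex columns.
#' @return area in squared input units.
#' @export
polygon_area <- function(poly) {
  x <- poly$x; y <- poly$y
  n <- length(x)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Even-odd point-in-polygon test
#'
#' @param px,py point coordinates (vectorized).
#' @param poly data.frame with \code{x}, \code{y} vertex columns.
#' @return logical vector; points exactly on an edge may fall on either side
#'   (callers treating the boundary specially should test distance == 0).
#' @export
point_in_polygon <- function(px, py, poly) {
  x <- poly$x; y <- poly$y
  n <- length(x)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((y[i] > py) != (y[j] > py)) &
      (px < (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Minimum distance from each point to a set of segments given as vectors of
# endpoints. Loops over segments (few) and vectorizes over points (many),
# keeping a running minimum. Used internally for distances to polygon
# boundaries.
.dist_to_segments <- function(px, py, x1, y1, x2, y2) {
  best <- rep(Inf, length(px))
  for (k in seq_along(x1)) {
    dx <- x2[k] - x1[k]; dy <- y2[k] - y1[k]
    len2 <- dx^2 + dy^2
    if (len2 == 0) len2 <- 1e-300    # degenerate segment = point
    t <- ((px - x1[k]) * dx + (py - y1[k]) * dy) / len2
    t <- pmin(1, pmax(0, t))
    d2 <- (px - (x1[k] + t * dx))^2 + (py - (y1[k] + t * dy))^2
    best <- pmin(best, d2)
  }
  sqrt(best)
}

#' Signed Euclidean distance from points to a region boundary
#'
#' Distance to the nearest boundary edge of any polygon in the region,
#' negative for points inside the region (inside any polygon), positive
#' outside, zero on the boundary.
#'
#' @param px,py point coordinates in µm (vectorized).
#' @param boundary a \code{region_boundary} object (see
#'   [infer_region_boundary()]) or any list with a \code{polygons} element.
#' @return numeric vector of signed distances in µm.
#' @export
signed_distance_to_boundary <- function(px, py, boundary) {
  polys <- boundary$polygons
  if (!length(polys)) stop("boundary has no polygons")
  x1 <- y1 <- x2 <- y2 <- numeric(0)
  for (p in polys) {
    n <- nrow(p)
    j <- c(seq.int(2, n), 1)
    x1 <- c(x1, p$x); y1 <- c(y1, p$y)
    x2 <- c(x2, p$x[j]); y2 <- c(y2, p$y[j])
  }
  d <- .dist_to_segments(px, py, x1, y1, x2, y2)
  inside <- rep(FALSE, length(px))
  for (p in polys) inside <- inside | point_in_polygon(px, py, p)
  ifelse(inside, -d, d)
}
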