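#' Closed polygon delineating a neovascularization
#'
#' Ordered vertex list in 0-based pixel coordinates (x = column, y = row,
#' pixel centers at integer coordinates). The polygon is implicitly closed
#' (last vertex connects to the first) and tagged with the image plane it was
#' drawn on.
#'
#' @param vertices two-column numeric matrix (x, y) or a list of
#'   length-2 vectors, at least 3 vertices.
#' @param plane which image the delineation refers to: `"angio"`,
#'   `"structure"`, or `"bscan"`.
#' @return An object of class `roi_polygon`.
#' @export
roi_polygon <- function(vertices, plane = c("angio", "structure", "bscan")) {
  plane <- match.arg(plane)
  if (is.list(vertices)) vertices <- do.call(rbind, vertices)
  vertices <- as.matrix(vertices)
  if (!is.numeric(vertices) || ncol(vertices) != 2L || nrow(vertices) < 3L)
    stop("roi_polygon: need >= 3 (x, y) vertices", call. = FALSE)
  colnames(vertices) <- c("x", "y")
  structure(list(vertices = vertices, plane = plane), class = "roi_polygon")
}

#' @export
print.roi_polygon <- function(x, ...) {
  cat(sprintf("roi_polygon (%s plane): %d vertices, area %.2f px^2\n",
              x$plane, nrow(x$vertices), abs(polygon_area(x))))
  invisible(x)
}

#' Signed polygon area (shoelace formula)
#'
#' @param roi an [roi_polygon()] or a two-column (x, y) vertex matrix.
#' @return Signed area in squared pixel units (positive if vertices are
#'   counter-clockwise in a y-down image coordinate system is negative;
#'   take `abs()` for the geometric area).
#' @export
polygon_area <- function(roi) {
  v <- if (inherits(roi, "roi_polygon")) roi$vertices else as.matrix(roi)
  x <- v[, 1]; y <- v[, 2]
  j <- c(seq_len(nrow(v))[-1], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

# Is point (px, py) on the closed polygon boundary (within eps)?
on_polygon_boundary <- function(px, py, v, eps = 1e-9) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  hit <- rep(FALSE, length(px))
  for (e in seq_len(n)) {
    x1 <- v[e, 1]; y1 <- v[e, 2]; x2 <- v[j[e], 1]; y2 <- v[j[e], 2]
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    if (len2 == 0) {
      d2 <- (px - x1)^2 + (py - y1)^2
      hit <- hit | d2 <= eps
      next
    }
    tt <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2))
    d2 <- (px - (x1 + tt * dx))^2 + (py - (y1 + tt * dy))^2
    hit <- hit | d2 <= eps
  }
  hit
}

# Even-odd point-in-polygon test for vectors of points (classic crossing
# count); boundary handling is left to the caller.
even_odd_inside <- function(px, py, v) {
  n <- nrow(v)
  j <- c(n, seq_len(n - 1L))
  inside <- rep(FALSE, length(px))
  for (e in seq_len(n)) {
    xi <- v[e, 1]; yi <- v[e, 2]
    xj <- v[j[e], 1]; yj <- v[j[e], 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
  }
  inside
}

#' Rasterize a polygon ROI to a pixel mask
#'
#' A pixel belongs to the mask iff its center satisfies the even-odd rule for
#' the closed polygon. Pixel centers sit at integer coordinates, 0-based;
#' a center lying exactly on a polygon edge is counted INSIDE (deterministic
#' tie-break). The result is deterministic.
#'
#' @param roi an [roi_polygon()].
#' @param shape image shape as `c(nrow, ncol)` (rows = y, columns = x).
#' @return A [binary_image()] of the given shape.
#' @export
polygon_to_mask <- function(roi, shape) {
  if (!inherits(roi, "roi_polygon"))
    stop("polygon_to_mask: 'roi' must be an roi_polygon", call. = FALSE)
  v <- roi$vertices
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  if (any(v[, 1] < -0.5 | v[, 1] > nc - 0.5 | v[, 2] < -0.5 | v[, 2] > nr - 0.5))
    stop("polygon_to_mask: polygon extends outside image bounds",
         call. = FALSE)
  # restrict the point test to the polygon's bounding box
  x0 <- max(0L, floor(min(v[, 1]))); x1 <- min(nc - 1L, ceiling(max(v[, 1])))
  y0 <- max(0L, floor(min(v[, 2]))); y1 <- min(nr - 1L, ceiling(max(v[, 2])))
  g <- expand.grid(x = x0:x1, y = y0:y1)
  ins <- even_odd_inside(g$x, g$y, v) | on_polygon_boundary(g$x, g$y, v)
  m <- matrix(FALSE, nr, nc)
  m[cbind(g$y + 1L, g$x + 1L)] <- ins
  binary_image(m)
}
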