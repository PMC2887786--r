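#' @useDynLib sirmap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm rpois rgamma rmultinom quantile var sd
#'   qgamma aggregate median setNames
#' @importFrom utils head read.csv write.csv
"_PACKAGE"

## Polygons are stored as an "area_polygons" object: a list of n vertex
## matrices (k x 2, open ring, counter-clockwise), parallel character IDs,
## and the rectangular window they tile.

new_area_polygons <- function(ids, polygons, window) {
  stopifnot(length(ids) == length(polygons), !anyDuplicated(ids))
  structure(list(ids = as.character(ids), polygons = polygons,
                 window = window),
            class = "area_polygons")
}

#' @export
print.area_polygons <- function(x, ...) {
  cat(sprintf("<area_polygons: %d areas in window [%g, %g] x [%g, %g]>\n",
              length(x$ids), x$window[1], x$window[3],
              x$window[2], x$window[4]))
  invisible(x)
}

#' @export
plot.area_polygons <- function(x, col = NA, border = "grey30", ...) {
  graphics::plot(NA, xlim = x$window[c(1, 3)], ylim = x$window[c(2, 4)],
                 asp = 1, xlab = "", ylab = "", ...)
  col <- rep_len(col, length(x$polygons))
  for (i in seq_along(x$polygons)) {
    graphics::polygon(x$polygons[[i]], col = col[i], border = border)
  }
  invisible(x)
}

# Sutherland-Hodgman clip of a convex polygon against half-plane
# a*x + b*y <= c.  Returns a (possibly empty) vertex matrix.
clip_halfplane <- function(poly, a, b, cc) {
  n <- nrow(poly)
  if (n == 0L) return(poly)
  d <- a * poly[, 1] + b * poly[, 2] - cc
  inside <- d <= 0
  if (all(inside)) return(poly)
  if (!any(inside)) return(poly[0, , drop = FALSE])
  out <- matrix(0, n + 4L, 2L)
  m <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (inside[i]) {
      m <- m + 1L; out[m, ] <- poly[i, ]
    }
    if (inside[i] != inside[j]) {
      t <- d[i] / (d[i] - d[j])
      m <- m + 1L
      out[m, ] <- poly[i, ] + t * (poly[j, ] - poly[i, ])
    }
  }
  out[seq_len(m), , drop = FALSE]
}

# Voronoi cell of point i among points `pts`, clipped to the rectangle
# `win` = c(xmin, ymin, xmax, ymax).  Nearer generators are applied first
# so the search can stop once the bisector cannot reach the current cell.
voronoi_cell <- function(i, pts, win) {
  cell <- rbind(c(win[1], win[2]), c(win[3], win[2]),
                c(win[3], win[4]), c(win[1], win[4]))
  p <- pts[i, ]
  d2 <- (pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2
  ord <- order(d2)
  ord <- ord[ord != i]
  for (j in ord) {
    rmax2 <- max((cell[, 1] - p[1])^2 + (cell[, 2] - p[2])^2)
    if (d2[j] > 4 * rmax2) break
    q <- pts[j, ]
    cell <- clip_halfplane(cell, 2 * (q[1] - p[1]), 2 * (q[2] - p[2]),
                           sum(q^2) - sum(p^2))
    if (nrow(cell) == 0L) break
  }
  cell
}

#' Generate an irregular synthetic tessellation
#'
#' Produces `n_areas` non-overlapping polygons tiling the unit square:
#' the Voronoi cells of uniformly random generator points, clipped to the
#' window.  The irregular cells emulate small administrative areas such
#' as census dissemination areas, which are far from a regular grid.
#'
#' @param n_areas number of areas (>= 1).
#' @param seed integer seed; the same seed reproduces the identical layer.
#' @return An `area_polygons` object with unique string IDs.
#' @examples
#' geo <- generate_geometry(12, seed = 1)
#' sum(vapply(geo$polygons, polygon_area, 0))  # == 1, the window area
#' @export
generate_geometry <- function(n_areas, seed = NULL) {
  if (!is.numeric(n_areas) || length(n_areas) != 1L || n_areas < 1)
    stop("`n_areas` must be a single integer >= 1")
  n_areas <- as.integer(n_areas)
  if (!is.null(seed)) set.seed(seed)
  win <- c(0, 0, 1, 1)
  ids <- sprintf("A%0*d", max(3L, nchar(n_areas)), seq_len(n_areas))
  if (n_areas == 1L) {
    sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
    return(new_area_polygons(ids, list(sq), win))
  }
  pts <- cbind(runif(n_areas), runif(n_areas))
  polys <- lapply(seq_len(n_areas), voronoi_cell, pts = pts, win = win)
  new_area_polygons(ids, polys, win)
}

#' Polygon area by the shoelace formula
#' @param poly a k x 2 vertex matrix (open ring).
#' @return Absolute enclosed area.
#' @export
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

#' Polygon centroid
#' @param poly a k x 2 vertex matrix (open ring).
#' @return Length-2 numeric (x, y).
#' @export
polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  cr <- x * ys - xs * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-300) return(colMeans(poly))
  c(sum((x + xs) * cr), sum((y + ys) * cr)) / (6 * a)
}

#' Centroids of all areas in a polygon layer
#' @param layer an `area_polygons` object.
#' @return n x 2 matrix of centroids, rownames = area IDs.
#' @export
area_centroids <- function(layer) {
  stopifnot(inherits(layer, "area_polygons"))
  m <- t(vapply(layer$polygons, polygon_centroid, numeric(2)))
  rownames(m) <- layer$ids
  colnames(m) <- c("x", "y")
  m
}
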