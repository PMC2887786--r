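## First-order contiguity: the neighbourhood structure shared by the
## Moran screen (as spatial weights) and the BYM model (as the ICAR
## graph).  Queen contiguity (any shared boundary point) is the default
## rule for irregular administrative polygons; rook (shared boundary of
## positive length) is available by flag.

new_adjacency <- function(ids, neighbours) {
  structure(list(ids = as.character(ids), neighbours = neighbours,
                 islands = lengths(neighbours) == 0L),
            class = "adjacency")
}

#' Construct an adjacency structure from explicit neighbour sets
#'
#' @param ids character vector of unique area IDs.
#' @param neighbours list (parallel to `ids`) of integer indices or
#'   character IDs of each area's neighbours.
#' @return An `adjacency` object (symmetrized, self-loops removed).
#' @export
adjacency <- function(ids, neighbours) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicate area IDs")
  nb <- lapply(seq_along(ids), function(i) {
    x <- neighbours[[i]]
    if (is.character(x)) x <- match(x, ids)
    if (anyNA(x)) stop("unknown neighbour ID for area ", ids[i])
    sort(unique(as.integer(x[x != i])))
  })
  # symmetrize
  for (i in seq_along(nb)) for (j in nb[[i]]) {
    if (!(i %in% nb[[j]])) nb[[j]] <- sort(c(nb[[j]], i))
  }
  new_adjacency(ids, nb)
}

#' @export
print.adjacency <- function(x, ...) {
  cat(sprintf("<adjacency: %d areas, %d edges, %d island(s)>\n",
              length(x$ids), sum(lengths(x$neighbours)) / 2,
              sum(x$islands)))
  invisible(x)
}

# squared point-to-segment distances, vectorized over points
pts_seg_dist2 <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  l2 <- dx * dx + dy * dy
  t <- ifelse(l2 > 0, ((px - ax) * dx + (py - ay) * dy) / l2, 0)
  t <- pmin(1, pmax(0, t))
  (px - (ax + t * dx))^2 + (py - (ay + t * dy))^2
}

# Minimum boundary distance between two polygons, plus whether they
# share a boundary segment of positive length (rook contact).
boundary_contact <- function(pa, pb, tol) {
  na <- nrow(pa); nb <- nrow(pb)
  a1 <- pa; a2 <- pa[c(2:na, 1), , drop = FALSE]
  b1 <- pb; b2 <- pb[c(2:nb, 1), , drop = FALSE]
  ia <- rep(seq_len(na), times = nb)
  ib <- rep(seq_len(nb), each = na)
  # endpoint-to-opposite-segment distances cover all touching contacts
  d2 <- pmin(
    pts_seg_dist2(b1[ib, 1], b1[ib, 2], a1[ia, 1], a1[ia, 2], a2[ia, 1], a2[ia, 2]),
    pts_seg_dist2(b2[ib, 1], b2[ib, 2], a1[ia, 1], a1[ia, 2], a2[ia, 1], a2[ia, 2]),
    pts_seg_dist2(a1[ia, 1], a1[ia, 2], b1[ib, 1], b1[ib, 2], b2[ib, 1], b2[ib, 2]),
    pts_seg_dist2(a2[ia, 1], a2[ia, 2], b1[ib, 1], b1[ib, 2], b2[ib, 1], b2[ib, 2]))
  touch <- sqrt(d2) <= tol
  if (!any(touch)) return(list(queen = FALSE, rook = FALSE))
  # rook: a collinear pair of segments overlapping by more than tol
  ux <- a2[ia, 1] - a1[ia, 1]; uy <- a2[ia, 2] - a1[ia, 2]
  ul <- sqrt(ux^2 + uy^2)
  ux <- ux / ul; uy <- uy / ul
  c1 <- abs(ux * (b1[ib, 2] - a1[ia, 2]) - uy * (b1[ib, 1] - a1[ia, 1]))
  c2 <- abs(ux * (b2[ib, 2] - a1[ia, 2]) - uy * (b2[ib, 1] - a1[ia, 1]))
  t1 <- ux * (b1[ib, 1] - a1[ia, 1]) + uy * (b1[ib, 2] - a1[ia, 2])
  t2 <- ux * (b2[ib, 1] - a1[ia, 1]) + uy * (b2[ib, 2] - a1[ia, 2])
  lo <- pmax(0, pmin(t1, t2))
  hi <- pmin(ul, pmax(t1, t2))
  rook <- any(c1 <= tol & c2 <= tol & (hi - lo) > tol)
  list(queen = TRUE, rook = rook)
}

#' Build first-order contiguity from a polygon layer
#'
#' @param layer an `area_polygons` object with unique IDs and valid
#'   (non-empty, finite) vertex rings.
#' @param rule `"queen"` (default: any shared boundary point) or
#'   `"rook"` (shared boundary of positive length).
#' @param tol snapping tolerance for boundary coincidence.
#' @return An `adjacency` object.  Areas with no neighbours are flagged
#'   as islands, not dropped.
#' @export
build_adjacency <- function(layer, rule = c("queen", "rook"), tol = 1e-8) {
  stopifnot(inherits(layer, "area_polygons"))
  rule <- match.arg(rule)
  if (anyDuplicated(layer$ids)) stop("duplicate area IDs in polygon layer")
  n <- length(layer$ids)
  for (i in seq_len(n)) {
    p <- layer$polygons[[i]]
    if (!is.matrix(p) || nrow(p) < 3L || anyNA(p) || any(!is.finite(p)))
      stop("invalid geometry for area ", layer$ids[i])
  }
  bb <- t(vapply(layer$polygons, function(p)
    c(min(p[, 1]), min(p[, 2]), max(p[, 1]), max(p[, 2])), numeric(4)))
  nb <- rep(list(integer(0)), n)
  for (i in seq_len(n - 1L)) {
    # bounding-box prescreen
    js <- which(bb[, 1] <= bb[i, 3] + tol & bb[, 3] >= bb[i, 1] - tol &
                bb[, 2] <= bb[i, 4] + tol & bb[, 4] >= bb[i, 2] - tol)
    js <- js[js > i]
    for (j in js) {
      ct <- boundary_contact(layer$polygons[[i]], layer$polygons[[j]], tol)
      hit <- if (rule == "queen") ct$queen else ct$rook
      if (hit) {
        nb[[i]] <- c(nb[[i]], j)
        nb[[j]] <- c(nb[[j]], i)
      }
    }
  }
  new_adjacency(layer$ids, lapply(nb, sort))
}

#' Rook/queen lattice adjacency for a regular grid
#'
#' Convenience constructor for the rectangular lattices used in
#' simulation studies; areas are numbered row-major.
#'
#' @param nrow,ncol lattice dimensions.
#' @param rule `"rook"` (default, 4-neighbour) or `"queen"`.
#' @return An `adjacency` object with IDs `"r<i>c<j>"`.
#' @export
lattice_adjacency <- function(nrow, ncol, rule = c("rook", "queen")) {
  rule <- match.arg(rule)
  idx <- function(r, c) as.integer((r - 1L) * ncol + c)
  ids <- as.vector(t(outer(seq_len(nrow), seq_len(ncol),
                           function(r, c) sprintf("r%dc%d", r, c))))
  nb <- vector("list", nrow * ncol)
  steps <- if (rule == "rook") {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  }
  for (r in seq_len(nrow)) for (c in seq_len(ncol)) {
    k <- idx(r, c)
    nbs <- integer(0)
    for (s in steps) {
      rr <- r + s[1]; cc <- c + s[2]
      if (rr >= 1 && rr <= nrow && cc >= 1 && cc <= ncol)
        nbs <- c(nbs, idx(rr, cc))
    }
    nb[[k]] <- sort(nbs)
  }
  new_adjacency(ids, nb)
}

#' Connected components of an adjacency graph
#' @param adj an `adjacency` object.
#' @return Integer component membership per area.
#' @export
graph_components <- function(adj) {
  n <- length(adj$ids)
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    k <- k + 1L
    queue <- s
    comp[s] <- k
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj$neighbours[[v]]) if (is.na(comp[w])) {
        comp[w] <- k
        queue <- c(queue, w)
      }
    }
  }
  comp
}

#' Breadth-first graph distances from a source area
#' @param adj an `adjacency` object.
#' @param from index or ID of the source area.
#' @return Integer distances (Inf for unreachable areas).
#' @export
graph_distance <- function(adj, from) {
  if (is.character(from)) from <- match(from, adj$ids)
  if (is.na(from)) stop("unknown source area")
  n <- length(adj$ids)
  d <- rep(Inf, n)
  d[from] <- 0
  queue <- from
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj$neighbours[[v]]) if (is.infinite(d[w])) {
      d[w] <- d[v] + 1
      queue <- c(queue, w)
    }
  }
  d
}

#' Row-standardized spatial weights
#'
#' Binary contiguity weights divided by each area's neighbour count, the
#' conventional style for Moran's I.  Island rows are all zero.
#'
#' @param adj an `adjacency` object.
#' @return A `spatial_weights` object.
#' @export
row_standardized_weights <- function(adj) {
  stopifnot(inherits(adj, "adjacency"))
  w <- lapply(adj$neighbours, function(nbs)
    if (length(nbs)) rep(1 / length(nbs), length(nbs)) else numeric(0))
  structure(list(ids = adj$ids, neighbours = adj$neighbours, weights = w,
                 style = "W"), class = "spatial_weights")
}

#' Binary (0/1) spatial weights
#' @param adj an `adjacency` object.
#' @return A `spatial_weights` object with unit weights.
#' @export
binary_weights <- function(adj) {
  stopifnot(inherits(adj, "adjacency"))
  w <- lapply(adj$neighbours, function(nbs) rep(1, length(nbs)))
  structure(list(ids = adj$ids, neighbours = adj$neighbours, weights = w,
                 style = "B"), class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("<spatial_weights: %d areas, style %s>\n",
              length(x$ids), x$style))
  invisible(x)
}

#' Validate an adjacency structure
#'
#' @param adj an `adjacency` object.
#' @return A list report: `symmetry_violations` (i, j index pairs),
#'   `self_loops` (indices), `islands` (IDs), `n_components`, and the
#'   per-area `components` membership.
#' @export
validate_adjacency <- function(adj) {
  stopifnot(inherits(adj, "adjacency"))
  sym <- list()
  self <- integer(0)
  for (i in seq_along(adj$ids)) {
    nbs <- adj$neighbours[[i]]
    if (i %in% nbs) self <- c(self, i)
    for (j in nbs) if (!(i %in% adj$neighbours[[j]]))
      sym[[length(sym) + 1L]] <- c(i, j)
  }
  comp <- graph_components(adj)
  list(symmetry_violations = sym, self_loops = self,
       islands = adj$ids[adj$islands],
       n_components = max(comp), components = comp)
}

#' Write / read adjacency as an edge-list CSV
#'
#' Columns `area_i`, `area_j`, one row per undirected edge (i < j);
#' islands are preserved through a second block of `area_i` rows with
#' empty `area_j`.
#'
#' @param adj an `adjacency` object.
#' @param path file path.
#' @return `read_adjacency` returns the `adjacency`; `write_adjacency`
#'   its input, invisibly.
#' @export
write_adjacency <- function(adj, path) {
  rows <- list()
  for (i in seq_along(adj$ids)) {
    js <- adj$neighbours[[i]]
    js <- js[js > i]
    if (length(js))
      rows[[length(rows) + 1L]] <-
        data.frame(area_i = adj$ids[i], area_j = adj$ids[js])
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(area_i = character(0), area_j = character(0))
  if (any(adj$islands))
    df <- rbind(df, data.frame(area_i = adj$ids[adj$islands], area_j = ""))
  write.csv(df, path, row.names = FALSE)
  invisible(adj)
}

#' @rdname write_adjacency
#' @param ids optional full ID vector (otherwise inferred from the file).
#' @export
read_adjacency <- function(path, ids = NULL) {
  df <- read.csv(path, colClasses = "character")
  if (is.null(ids))
    ids <- sort(unique(c(df$area_i, df$area_j[nzchar(df$area_j)])))
  nb <- rep(list(character(0)), length(ids))
  names(nb) <- ids
  keep <- nzchar(df$area_j)
  for (k in which(keep)) {
    nb[[df$area_i[k]]] <- c(nb[[df$area_i[k]]], df$area_j[k])
    nb[[df$area_j[k]]] <- c(nb[[df$area_j[k]]], df$area_i[k])
  }
  adjacency(ids, nb)
}
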