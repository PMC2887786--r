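# Fixtures built in code: grid polygon layers, simple stratum tables.

# nr x nc grid of unit squares, row-major IDs g<r>_<c>
grid_layer <- function(nr, nc) {
  ids <- character(0)
  polys <- list()
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    ids <- c(ids, sprintf("g%d_%d", r, c))
    x0 <- c - 1; y0 <- r - 1
    polys[[length(polys) + 1L]] <-
      rbind(c(x0, y0), c(x0 + 1, y0), c(x0 + 1, y0 + 1), c(x0, y0 + 1))
  }
  sirmap:::new_area_polygons(ids, polys, c(0, 0, nc, nr))
}

# one-stratum table: one age band, one sex, given per-area pop/cases
simple_strata <- function(ids, population, cases) {
  data.frame(area_id = ids, age_band = "all", sex = "A",
             population = population, cases = cases,
             stringsAsFactors = FALSE)
}

# dense weight matrix from a spatial_weights object (for oracles)
dense_W <- function(w) {
  n <- length(w$ids)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nbs <- w$neighbours[[i]]
    if (length(nbs)) W[i, nbs] <- w$weights[[i]]
  }
  W
}

# random symmetric adjacency on n nodes (no guarantee of connectivity)
random_adjacency <- function(n, p = 0.4) {
  nb <- rep(list(integer(0)), n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < p) {
      nb[[i]] <- c(nb[[i]], j)
      nb[[j]] <- c(nb[[j]], i)
    }
  }
  adjacency(sprintf("n%02d", seq_len(n)), nb)
}
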