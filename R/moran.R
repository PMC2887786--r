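## Spatial-autocorrelation screening.  Global Moran's I on the SIR
## surface, with inference by a Poisson parametric bootstrap: replicate
## counts are drawn independently as Y* ~ Poisson(E) under the
## constant-risk null, so the null distribution automatically accounts
## for the wildly different population sizes of small areas.  A
## one-tailed test for positive autocorrelation only, with Bonferroni
## control across the family of outcomes screened.

# flatten a spatial_weights object (optionally restricted to a subset
# of areas) into directed edge vectors
weights_edges <- function(w, keep = NULL) {
  n <- length(w$ids)
  if (is.null(keep)) keep <- rep(TRUE, n)
  map <- cumsum(keep)           # old index -> new index
  ie <- je <- integer(0)
  we <- numeric(0)
  for (i in which(keep)) {
    nbs <- w$neighbours[[i]]
    ok <- keep[nbs]
    if (!any(ok)) next
    ie <- c(ie, rep(map[i], sum(ok)))
    je <- c(je, map[nbs[ok]])
    we <- c(we, w$weights[[i]][ok])
  }
  list(i = ie, j = je, w = we)
}

#' Global Moran's I
#'
#' I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2 with z the
#' deviations from the mean over the included areas.  Masked areas (and
#' their edges) contribute nothing.
#'
#' @param x numeric values per area (conforming to `weights`).
#' @param weights a `spatial_weights` object.
#' @param mask optional logical; `TRUE` marks an area to exclude.
#' @return The Moran statistic (scalar).
#' @export
morans_i <- function(x, weights, mask = NULL) {
  stopifnot(inherits(weights, "spatial_weights"))
  n_all <- length(weights$ids)
  if (length(x) != n_all) stop("values do not conform to the weights")
  keep <- if (is.null(mask)) rep(TRUE, n_all) else !mask
  keep <- keep & !is.na(x)
  n <- sum(keep)
  if (n < 3L) stop("Moran's I needs at least 3 included areas")
  ed <- weights_edges(weights, keep)
  s0 <- sum(ed$w)
  if (s0 <= 0) stop("all retained weights are zero")
  z <- x[keep] - mean(x[keep])
  den <- sum(z^2)
  if (den == 0)
    stop(structure(class = c("sirmap_undefined_statistic", "error",
                             "condition"),
                   list(message = "Moran's I undefined: zero variance",
                        call = sys.call(-1))))
  (n / s0) * sum(ed$w * z[ed$i] * z[ed$j]) / den
}

#' Moran's I by an explicit O(n^2) double loop
#'
#' Reference implementation over the dense weight matrix, kept separate
#' from [morans_i()] as an independent cross-check.
#'
#' @param x numeric values per area.
#' @param W dense n x n weight matrix.
#' @return The Moran statistic.
#' @export
morans_i_dense <- function(x, W) {
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    num <- num + W[i, j] * z[i] * z[j]
  (n / sum(W)) * num / sum(z^2)
}

#' Parametric bootstrap Moran test
#'
#' Computes Moran's I of the observed SIRs (Y/E), then draws B
#' replicate count vectors Y* with independent Poisson(E) entries,
#' recomputes I on Y*/E, and reports the one-tailed Monte-Carlo
#' p-value `(1 + #\{I* >= I_obs\}) / (B + 1)`.  Areas with E = 0 are
#' masked throughout.  Replicates whose simulated surface is constant
#' (zero variance) are recorded as non-exceeding.
#'
#' @param Y observed counts per area.
#' @param E expected counts per area (>= 0; zeros masked).
#' @param weights a `spatial_weights` object conforming to Y/E.
#' @param B number of bootstrap replicates (>= 1).
#' @param seed integer seed.
#' @param retain_replicates keep the replicate statistics in the result.
#' @return A `moran_result` list: `statistic`, `p_value`, `B`, `seed`,
#'   and optionally `replicates`.
#' @export
parametric_bootstrap_p <- function(Y, E, weights, B = 999L, seed = NULL,
                                   retain_replicates = FALSE) {
  stopifnot(inherits(weights, "spatial_weights"))
  if (B < 1) stop("B must be >= 1")
  if (any(E < 0)) stop("E must be >= 0")
  if (all(E == 0)) stop("all expected counts are zero")
  if (!is.null(seed)) set.seed(seed)
  n_all <- length(weights$ids)
  if (length(Y) != n_all || length(E) != n_all)
    stop("Y/E do not conform to the weights")
  keep <- E > 0
  n <- sum(keep)
  if (n < 3L) stop("fewer than 3 areas with positive expected count")
  ed <- weights_edges(weights, keep)
  s0 <- sum(ed$w)
  if (s0 <= 0) stop("no edges among areas with positive expected count")
  Ek <- E[keep]
  moran_of <- function(v) {
    z <- v - mean(v)
    den <- sum(z^2)
    if (den == 0) return(NA_real_)
    (n / s0) * sum(ed$w * z[ed$i] * z[ed$j]) / den
  }
  i_obs <- moran_of(Y[keep] / Ek)
  if (is.na(i_obs)) stop("observed SIR surface has zero variance")
  ystar <- matrix(rpois(n * B, Ek), nrow = n)
  zs <- ystar / Ek
  zs <- sweep(zs, 2, colMeans(zs))
  den <- colSums(zs^2)
  num <- colSums(ed$w * zs[ed$i, , drop = FALSE] *
                   zs[ed$j, , drop = FALSE])
  istar <- ifelse(den == 0, NA_real_, (n / s0) * num / den)
  exceed <- !is.na(istar) & istar >= i_obs   # zero-variance: non-exceeding
  res <- list(statistic = i_obs,
              p_value = (1 + sum(exceed)) / (B + 1),
              B = as.integer(B), n = n, seed = seed)
  if (retain_replicates) res$replicates <- istar
  structure(res, class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f, parametric bootstrap p = %.4g (B = %d)\n",
              x$statistic, x$p_value, x$B))
  invisible(x)
}

#' Bonferroni screen over a family of Moran tests
#'
#' Flags an outcome for downstream hierarchical modelling when its
#' one-tailed bootstrap p-value is below `alpha / m` *and* its Moran
#' statistic is positive (a negative I never indicates clustering).
#'
#' @param results data.frame with columns `site`, `moran_i`, `p_value`
#'   (extra columns pass through), or a named list of `moran_result`s.
#' @param alpha family-wise error level.
#' @param m family size; must be at least the number of sites tested
#'   (default: the number of sites).
#' @return A `screen_table` data.frame adding `m`, `alpha`, `threshold`,
#'   `flagged`.
#' @export
bonferroni_screen <- function(results, alpha = 0.05, m = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  if (is.list(results) && !is.data.frame(results)) {
    results <- data.frame(
      site = if (is.null(names(results))) as.character(seq_along(results))
             else names(results),
      moran_i = vapply(results, function(r) r$statistic, 0),
      p_value = vapply(results, function(r) r$p_value, 0),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  if (is.null(m)) m <- nrow(results)
  if (m < nrow(results)) stop("family size m smaller than number of sites")
  out <- results
  out$m <- as.integer(m)
  out$alpha <- alpha
  out$threshold <- alpha / m
  out$flagged <- out$p_value < out$threshold & out$moran_i > 0
  structure(out, class = c("screen_table", "data.frame"))
}
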