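## Circular Kulldorff-style Poisson spatial scan.  Candidate zones grow
## around each area centroid by ascending centroid distance under a cap
## on the zone's share of the total expected count; the scan statistic
## is the maximum Poisson log-likelihood ratio over zones, with
## Monte-Carlo inference by redistributing the observed total
## multinomially over areas with probabilities proportional to E
## (conditioning on the total).

#' Enumerate candidate scan zones
#'
#' For every centre, areas are ordered by centroid distance (ties by
#' index) and every prefix whose expected count stays within
#' `max_fraction` of the total is a zone; duplicate member sets are
#' dropped.
#'
#' @param centroids n x 2 matrix of area centroids.
#' @param E expected counts per area.
#' @param max_fraction maximum zone share of total E, in (0, 0.5].
#' @return List of integer membership vectors (area indices).
#' @export
enumerate_zones <- function(centroids, E, max_fraction = 0.5) {
  n <- nrow(centroids)
  if (is.null(n) || n == 0L) stop("no areas to scan")
  if (max_fraction <= 0 || max_fraction > 0.5)
    stop("max_fraction must be in (0, 0.5]")
  cap <- max_fraction * sum(E)
  zones <- list()
  seen <- new.env(hash = TRUE)
  for (c0 in seq_len(n)) {
    d <- (centroids[, 1] - centroids[c0, 1])^2 +
         (centroids[, 2] - centroids[c0, 2])^2
    ord <- order(d, seq_len(n))
    ez <- cumsum(E[ord])
    kmax <- max(which(ez <= cap), 0L)
    if (kmax == 0L) next
    for (k in seq_len(kmax)) {
      mem <- sort(ord[seq_len(k)])
      key <- paste(mem, collapse = ",")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      zones[[length(zones) + 1L]] <- mem
    }
  }
  zones
}

#' Kulldorff Poisson log-likelihood ratio for one zone
#'
#' `LLR = Y_z log(Y_z/E_z) + (Y_t - Y_z) log((Y_t - Y_z)/(E_t - E_z))`
#' when the inside rate exceeds the outside rate, else 0; zero counts
#' contribute 0.  Expectations are assumed conditioned so that
#' `E_total = Y_total`.
#'
#' @param Y_z,E_z zone observed and expected counts.
#' @param Y_total,E_total study totals.
#' @return The log-likelihood ratio (>= 0).
#' @export
poisson_llr <- function(Y_z, E_z, Y_total, E_total) {
  if (E_z <= 0 || E_z >= E_total) stop("E_z must be in (0, E_total)")
  Y_out <- Y_total - Y_z
  E_out <- E_total - E_z
  if (Y_z == 0) return(0)
  inside <- Y_z / E_z
  outside <- Y_out / E_out
  if (inside <= outside) return(0)
  t1 <- Y_z * log(Y_z / E_z)
  t2 <- if (Y_out > 0) Y_out * log(Y_out / E_out) else 0
  t1 + t2
}

# Prefix structure over all centres: for each centre the distance
# ordering and the largest prefix length within the expected-count cap.
# Candidate zones are exactly the prefixes (duplicates do not affect
# the maximum), so the max LLR per count vector reduces to vectorized
# cumulative sums.
zone_prefixes <- function(centroids, E, max_fraction) {
  n <- nrow(centroids)
  if (is.null(n) || n == 0L) stop("no areas to scan")
  if (max_fraction <= 0 || max_fraction > 0.5)
    stop("max_fraction must be in (0, 0.5]")
  cap <- max_fraction * sum(E)
  out <- vector("list", n)
  for (c0 in seq_len(n)) {
    d <- (centroids[, 1] - centroids[c0, 1])^2 +
         (centroids[, 2] - centroids[c0, 2])^2
    ord <- order(d, seq_len(n))
    ez <- cumsum(E[ord])
    kmax <- if (ez[1] > cap) 0L else max(which(ez <= cap))
    out[[c0]] <- list(ord = ord, ez = ez[seq_len(kmax)], kmax = kmax)
  }
  out
}

# max LLR over all prefix zones for one count vector (E conditioned so
# totals match inside)
scan_max_llr <- function(Y, E, prefixes) {
  Yt <- sum(Y)
  scale <- Yt / sum(E)
  best <- 0
  best_centre <- 0L
  best_k <- 0L
  for (c0 in seq_along(prefixes)) {
    pf <- prefixes[[c0]]
    if (pf$kmax == 0L) next
    yz <- cumsum(Y[pf$ord])[seq_len(pf$kmax)]
    ez <- pf$ez * scale
    yo <- Yt - yz
    eo <- Yt - ez
    ok <- yz > 0 & ez > 0 & eo > 0 & yz / ez > yo / eo
    if (!any(ok)) next
    llr <- rep(0, pf$kmax)
    t2 <- ifelse(yo > 0, yo * log(ifelse(yo > 0, yo, 1) / eo), 0)
    llr[ok] <- (yz * log(yz / ez) + t2)[ok]
    k <- which.max(llr)
    if (llr[k] > best) {
      best <- llr[k]
      best_centre <- c0
      best_k <- k
    }
  }
  list(llr = best, centre = best_centre, k = best_k)
}

#' Monte-Carlo Poisson spatial scan
#'
#' Finds the most likely high-rate zone and its Monte-Carlo p-value:
#' `n_sim` null replicates redistribute the observed case total over
#' areas multinomially with probabilities E/E_total, and
#' `p = (1 + #\{max LLR* >= max LLR_obs\}) / (n_sim + 1)`.
#'
#' @param Y observed counts per area.
#' @param E expected counts per area.
#' @param centroids n x 2 matrix of centroids.
#' @param max_fraction zone cap as share of total E.
#' @param n_sim number of null replicates (999 by convention).
#' @param seed integer seed.
#' @param ids optional area IDs for reporting.
#' @return A `scan_result`: most-likely zone members, `Y_z`, `E_z`
#'   (conditioned), inside/outside SIRs, `llr`, `p_value`, `n_sim`,
#'   `seed`.
#' @export
monte_carlo_scan <- function(Y, E, centroids, max_fraction = 0.5,
                             n_sim = 999L, seed = NULL, ids = NULL) {
  if (n_sim < 1) stop("n_sim must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ids)) ids <- as.character(seq_along(Y))
  prefixes <- zone_prefixes(centroids, E, max_fraction)
  if (all(vapply(prefixes, `[[`, 0L, "kmax") == 0L))
    stop("no candidate zones under the expected-count cap")
  obs <- scan_max_llr(Y, E, prefixes)
  Yt <- sum(Y)
  prob <- E / sum(E)
  exceed <- 0L
  for (b in seq_len(n_sim)) {
    Yb <- as.vector(rmultinom(1, Yt, prob))
    if (scan_max_llr(Yb, E, prefixes)$llr >= obs$llr) exceed <- exceed + 1L
  }
  mem <- if (obs$centre > 0L) {
    pf <- prefixes[[obs$centre]]
    sort(pf$ord[seq_len(obs$k)])
  } else integer(0)
  Ec <- E * (Yt / sum(E))
  Yz <- sum(Y[mem]); Ez <- sum(Ec[mem])
  inside_sir <- if (Ez > 0) Yz / Ez else NA_real_
  outside_sir <- if (Yt - Ez > 0) (Yt - Yz) / (Yt - Ez) else NA_real_
  structure(list(zone = ids[mem], zone_index = mem, Y_z = Yz, E_z = Ez,
                 inside_sir = inside_sir, outside_sir = outside_sir,
                 llr = obs$llr,
                 p_value = (1 + exceed) / (n_sim + 1),
                 n_sim = as.integer(n_sim), seed = seed),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf(paste0("Most likely cluster: %d areas, Y = %d, E = %.2f, ",
                     "SIR in/out = %.2f/%.2f\nLLR = %.4f, p = %.4g ",
                     "(%d simulations)\n"),
              length(x$zone), x$Y_z, x$E_z, x$inside_sir, x$outside_sir,
              x$llr, x$p_value, x$n_sim))
  invisible(x)
}

#' Write a scan result as a JSON report
#' @param result a `scan_result`.
#' @param path file path.
#' @return The input, invisibly.
#' @export
write_scan_report <- function(result, path) {
  jsonlite::write_json(
    list(zone = result$zone, Y_z = result$Y_z, E_z = result$E_z,
         inside_sir = result$inside_sir, outside_sir = result$outside_sir,
         llr = result$llr, p_value = result$p_value, n_sim = result$n_sim,
         seed = result$seed),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(result)
}
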