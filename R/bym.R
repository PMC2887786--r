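## Besag-York-Mollie hierarchical smoothing.  The area log relative
## risk is decomposed into a flat intercept, a spatially structured
## intrinsic-CAR effect u and an unstructured effect v, with Gamma
## hyperpriors on both precisions.  Inference is by MCMC (compiled
## single-site Metropolis sweeps with conjugate precision draws);
## convergence is monitored with the Gelman-Rubin diagnostic across
## over-dispersed chains.

#' MCMC settings for the BYM fit
#'
#' The `"desk"` protocol (default) is sized for interactive use and
#' simulation studies; `"replica"` applies the heavyweight protocol
#' used historically for registry analyses (3 chains, 100,000 burn-in,
#' 1,000,000 iterations with every 200th draw saved, i.e. 15,000 saved
#' draws and 3,000,000 post-burn-in iterations in total).
#'
#' @param n_chains number of chains (>= 2 for diagnostics).
#' @param burn_in discarded iterations per chain.
#' @param n_iter post-burn-in iterations per chain.
#' @param thin save every `thin`-th draw.
#' @param seed integer seed.
#' @param a_u,b_u shape and rate of the Gamma hyperprior on the
#'   structured precision 1/sigma_u^2 (default Gamma(0.5, 0.0005), the
#'   conventional disease-mapping choice).
#' @param a_v,b_v same for the unstructured precision.
#' @param init_dispersion scale of the over-dispersion of the chains'
#'   starting points.
#' @param protocol `"desk"` or `"replica"`; explicit arguments override
#'   the protocol's values.
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(n_chains = NULL, burn_in = NULL, n_iter = NULL,
                        thin = NULL, seed = NULL,
                        a_u = 0.5, b_u = 0.0005,
                        a_v = 0.5, b_v = 0.0005,
                        init_dispersion = 1,
                        protocol = c("desk", "replica")) {
  protocol <- match.arg(protocol)
  def <- if (protocol == "desk") {
    list(n_chains = 2L, burn_in = 5000L, n_iter = 20000L, thin = 10L)
  } else {
    list(n_chains = 3L, burn_in = 100000L, n_iter = 1000000L, thin = 200L)
  }
  cfg <- list(
    n_chains = as.integer(if (is.null(n_chains)) def$n_chains else n_chains),
    burn_in = as.integer(if (is.null(burn_in)) def$burn_in else burn_in),
    n_iter = as.integer(if (is.null(n_iter)) def$n_iter else n_iter),
    thin = as.integer(if (is.null(thin)) def$thin else thin),
    seed = seed, a_u = a_u, b_u = b_u, a_v = a_v, b_v = b_v,
    init_dispersion = init_dispersion, protocol = protocol)
  if (cfg$thin < 1) stop("thin must be >= 1")
  if (cfg$n_chains < 1) stop("need at least one chain")
  structure(cfg, class = "mcmc_config")
}

#' Saved-draw accounting for an MCMC configuration
#'
#' @param config an [mcmc_config()].
#' @return List with `per_chain` saved draws, `total_saved`, and
#'   `total_iterations` (post-burn-in sweeps over all chains).
#' @export
mcmc_accounting <- function(config) {
  per <- config$n_iter %/% config$thin
  list(per_chain = per,
       total_saved = config$n_chains * per,
       total_iterations = config$n_chains * config$n_iter)
}

# flatten an adjacency into 0-based CSR-ish arrays for the C++ sampler
flatten_adjacency <- function(adj) {
  idx <- unlist(adj$neighbours)
  list(nb_index = as.integer(if (length(idx)) idx - 1L else integer(0)),
       nb_start = as.integer(c(0L, cumsum(lengths(adj$neighbours)))))
}

#' Fit the BYM model
#'
#' Samples the posterior of `Y_i ~ Poisson(E_i * theta_i)`,
#' `log theta_i = alpha + u_i + v_i`, with an intrinsic CAR prior on u
#' (sum-to-zero, islands held at u = 0 and carried by v alone), iid
#' normal v, a flat intercept and Gamma hyperpriors on both precisions.
#'
#' @param Y observed counts per area (named or in adjacency order).
#' @param E expected counts per area, all > 0 (exclude unpopulated
#'   areas upstream).
#' @param adj an `adjacency` object covering the modelled areas.
#' @param config an [mcmc_config()].
#' @return A `bym_fit` object: per-chain saved draws of alpha, sigma_u,
#'   sigma_v, u and v, plus data, acceptance rates and settings.
#' @examples
#' adjl <- lattice_adjacency(4, 4)
#' E <- rep(25, 16)
#' Y <- rpois(16, E)
#' fit <- fit_bym(Y, E, adjl, mcmc_config(burn_in = 500, n_iter = 2000,
#'                                        thin = 2, seed = 1))
#' summary(fit)
#' @export
fit_bym <- function(Y, E, adj, config = mcmc_config()) {
  stopifnot(inherits(adj, "adjacency"), inherits(config, "mcmc_config"))
  n <- length(adj$ids)
  if (length(Y) != n || length(E) != n)
    stop("Y and E must cover every area in the adjacency")
  if (any(E <= 0))
    stop("non-positive expected count in the modelled set; ",
         "exclude unpopulated areas before fitting")
  if (any(Y < 0) || any(Y != floor(Y))) stop("Y must be integers >= 0")
  comp <- graph_components(adj)
  free <- !adj$islands
  sub_comp <- unique(comp[free])
  if (length(unique(comp)) > 1L)
    warning("adjacency graph is disconnected; the intrinsic prior ",
            "applies per component")
  icar_rank <- if (any(free)) sum(free) - length(sub_comp) else 0L
  fl <- flatten_adjacency(adj)
  if (!is.null(config$seed)) set.seed(config$seed)
  alpha_bar <- log(max(sum(Y), 0.5) / sum(E))
  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    disp <- config$init_dispersion
    alpha0 <- alpha_bar + disp * rnorm(1, 0, 0.5)
    u0 <- rnorm(n, 0, 0.2 * disp)
    u0[adj$islands] <- 0
    if (any(free)) u0[free] <- u0[free] - mean(u0[free])
    v0 <- rnorm(n, 0, 0.2 * disp)
    tau_u0 <- exp(rnorm(1, log(20), disp))
    tau_v0 <- exp(rnorm(1, log(20), disp))
    chains[[ch]] <- bym_mcmc_chain(
      as.integer(Y), as.numeric(E), fl$nb_index, fl$nb_start,
      adj$islands, as.integer(icar_rank),
      config$burn_in, config$n_iter, config$thin,
      config$a_u, config$b_u, config$a_v, config$b_v,
      alpha0, u0, v0, tau_u0, tau_v0)
  }
  structure(list(chains = chains, Y = as.integer(Y), E = as.numeric(E),
                 ids = adj$ids, islands = adj$islands, config = config,
                 icar_rank = icar_rank),
            class = "bym_fit")
}

# pooled (all chains) draw matrix of a per-area quantity
pool_draws <- function(fit, what = c("theta", "u", "v")) {
  what <- match.arg(what)
  do.call(rbind, lapply(fit$chains, function(ch) {
    switch(what,
           theta = exp(ch$alpha + ch$u + ch$v),
           u = ch$u, v = ch$v)
  }))
}

pool_scalar <- function(fit, what) {
  unlist(lapply(fit$chains, `[[`, what))
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Computed from between- and within-chain variances of the saved
#' draws.  Parameters whose within-chain variance is zero are reported
#' as `NA` (diagnostic undefined) rather than failing.
#'
#' @param fit a `bym_fit` (or a list of equal-length numeric vectors,
#'   one per chain, for a single parameter).
#' @param pars which parameters: any of `"alpha"`, `"sigma_u"`,
#'   `"sigma_v"`, `"theta"` (expands per area).
#' @return Named numeric vector of R-hat values.
#' @export
gelman_rubin <- function(fit, pars = c("alpha", "sigma_u", "sigma_v",
                                       "theta")) {
  if (!inherits(fit, "bym_fit")) {
    return(psrf(fit))
  }
  if (length(fit$chains) < 2L)
    stop("Gelman-Rubin diagnostic needs at least 2 chains")
  out <- numeric(0)
  for (p in pars) {
    if (p %in% c("alpha", "sigma_u", "sigma_v")) {
      out[p] <- psrf(lapply(fit$chains, `[[`, p))
    } else if (p %in% c("theta", "u", "v")) {
      mats <- lapply(fit$chains, function(ch)
        switch(p, theta = exp(ch$alpha + ch$u + ch$v), u = ch$u,
               v = ch$v))
      for (i in seq_along(fit$ids)) {
        out[sprintf("%s[%s]", p, fit$ids[i])] <-
          psrf(lapply(mats, function(m) m[, i]))
      }
    } else stop("unknown parameter selector: ", p)
  }
  out
}

# plain PSRF from a list of chains (numeric vectors of equal length)
psrf <- function(chains) {
  m <- length(chains)
  if (m < 2L) stop("need >= 2 chains")
  n <- length(chains[[1]])
  if (n < 10L) stop("need >= 10 draws per chain")
  means <- vapply(chains, mean, 0)
  vars <- vapply(chains, var, 0)
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Posterior summary per area
#'
#' Pooled over chains: posterior mean SIR, central 95% credible
#' interval, and the exceedance probability P(theta > 1 | data).
#'
#' @param fit a `bym_fit`.
#' @param exceed_at exceedance cut (default 1.0 = above-average risk).
#' @return Data.frame `area_id, smoothed_sir, cri_low, cri_high,
#'   exceedance`.
#' @export
summarize_posterior <- function(fit, exceed_at = 1.0) {
  th <- pool_draws(fit, "theta")
  if (nrow(th) < 100L) stop("need at least 100 saved draws")
  data.frame(area_id = fit$ids,
             smoothed_sir = colMeans(th),
             cri_low = apply(th, 2, quantile, 0.025, names = FALSE),
             cri_high = apply(th, 2, quantile, 0.975, names = FALSE),
             exceedance = colMeans(th > exceed_at),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Posterior spatial fraction
#'
#' Per saved draw, the share of random-effect variation attributable to
#' the spatially structured component:
#' `Var(u) / (Var(u) + Var(v))` with empirical across-area variances
#' (or the standard-deviation ratio `sd(u) / (sd(u) + sd(v))` with
#' `method = "sd"`).  Summarized by the posterior mean and central 95%
#' interval.
#'
#' @param fit a `bym_fit`.
#' @param method `"variance"` (default) or `"sd"`.
#' @return List `mean`, `ci_low`, `ci_high`, `draws`.
#' @export
spatial_fraction <- function(fit, method = c("variance", "sd")) {
  method <- match.arg(method)
  U <- pool_draws(fit, "u")
  V <- pool_draws(fit, "v")
  if (nrow(U) < 100L) stop("need at least 100 saved draws")
  vu <- apply(U, 1, var)
  vv <- apply(V, 1, var)
  if (method == "sd") { vu <- sqrt(vu); vv <- sqrt(vv) }
  tot <- vu + vv
  bad <- tot == 0
  if (any(bad)) {
    warning(sum(bad), " draw(s) with zero total variation skipped")
    vu <- vu[!bad]; tot <- tot[!bad]
  }
  fr <- vu / tot
  list(mean = mean(fr),
       ci_low = quantile(fr, 0.025, names = FALSE),
       ci_high = quantile(fr, 0.975, names = FALSE),
       draws = fr)
}
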