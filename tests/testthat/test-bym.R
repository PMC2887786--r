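quick_cfg <- function(seed, chains = 2L)
  mcmc_config(n_chains = chains, burn_in = 1000, n_iter = 4000, thin = 4,
              seed = seed)

test_that("MCMC accounting matches the configured protocol", {
  acc <- mcmc_accounting(mcmc_config(protocol = "replica"))
  expect_equal(acc$per_chain, 5000)
  expect_equal(acc$total_saved, 15000)
  expect_equal(acc$total_iterations, 3000000)
  desk <- mcmc_accounting(mcmc_config())
  expect_equal(desk$total_saved, 2 * 2000)
})

test_that("single neighbourless area reduces to a log-normal Poisson fit", {
  adj1 <- adjacency("solo", list(integer(0)))
  fit <- fit_bym(100L, 100, adj1, quick_cfg(1))
  post_mean <- unname(fitted(fit))
  # dense-integration oracle: flat prior on log(theta) (the flat
  # intercept absorbs the level), posterior ~ theta^Y exp(-E theta)
  l <- seq(-1.5, 1.5, length.out = 20001)
  w <- exp(100 * l - 100 * exp(l))
  oracle <- sum(exp(l) * w) / sum(w)
  expect_equal(oracle, 1.0, tolerance = 0.01)
  expect_gt(post_mean, 0.85)
  expect_lt(post_mean, 1.15)
  expect_lt(abs(post_mean - oracle), 0.1)
})

test_that("zero counts with tiny E are pulled up toward the field", {
  adj <- lattice_adjacency(5, 5)
  E <- rep(10, 25)
  E[13] <- 0.5
  set.seed(2)
  Y <- rpois(25, E)
  Y[13] <- 0L
  fit <- fit_bym(Y, E, adj, quick_cfg(3))
  expect_gt(unname(fitted(fit)["r3c3"]), 0.2)  # raw SIR is 0
})

test_that("non-positive expected counts are refused", {
  adj <- lattice_adjacency(2, 2)
  expect_error(fit_bym(c(1L, 2L, 1L, 0L), c(1, 1, 1, 0), adj,
                       quick_cfg(1)), "non-positive")
})

test_that("saved u draws are centred and theta positive in every draw", {
  adj <- lattice_adjacency(4, 4)
  set.seed(5)
  E <- runif(16, 10, 30)
  Y <- rpois(16, E)
  fit <- fit_bym(Y, E, adj, quick_cfg(6))
  for (ch in fit$chains) {
    expect_true(all(abs(rowSums(ch$u)) < 1e-9))
    expect_true(all(exp(ch$alpha + ch$u + ch$v) > 0))
  }
  acc <- mcmc_accounting(fit$config)
  expect_equal(nrow(fit$chains[[1]]$u), acc$per_chain)
})

test_that("posterior means shrink and stay within the raw SIR range", {
  set.seed(9)
  adj <- lattice_adjacency(6, 6)
  E <- rep(15, 36)
  Y <- rpois(36, E * exp(0.4 * rnorm(36)))
  fit <- fit_bym(Y, E, adj, quick_cfg(10))
  raw <- Y / E
  sm <- unname(fitted(fit))
  expect_lte(IQR(sm), IQR(raw))
  expect_gte(min(sm), min(raw))
  expect_lte(max(sm), max(raw))
})

test_that("with massive data the posterior tracks the raw SIRs", {
  adj <- lattice_adjacency(3, 3)
  E <- rep(10000, 9)
  theta <- c(0.8, 1, 1.2, 0.9, 1.1, 1, 0.95, 1.05, 1)
  set.seed(11)
  Y <- rpois(9, E * theta)
  fit <- fit_bym(Y, E, adj, quick_cfg(12))
  expect_true(all(abs(unname(fitted(fit)) / (Y / E) - 1) < 0.02))
})

test_that("relabelling areas permutes the fit (to Monte-Carlo error)", {
  set.seed(14)
  adj <- lattice_adjacency(4, 4)
  E <- runif(16, 15, 25)
  Y <- rpois(16, E)
  perm <- sample(16)
  padj <- adjacency(adj$ids[perm],
                    lapply(perm, function(i) adj$ids[adj$neighbours[[i]]]))
  f1 <- fit_bym(Y, E, adj, quick_cfg(15))
  f2 <- fit_bym(Y[perm], E[perm], padj, quick_cfg(15))
  m1 <- fitted(f1)[adj$ids[perm]]
  m2 <- fitted(f2)
  expect_lt(max(abs(m1 - m2)), 0.06)
})

test_that("islands keep u at zero and still get fitted risks", {
  nb <- lattice_adjacency(3, 3)$neighbours
  nb[[5]] <- integer(0)
  for (i in seq_along(nb)) nb[[i]] <- setdiff(nb[[i]], 5L)
  adj <- suppressWarnings(adjacency(sprintf("z%d", 1:9), nb))
  E <- rep(20, 9)
  set.seed(16)
  Y <- rpois(9, E)
  fit <- suppressWarnings(fit_bym(Y, E, adj, quick_cfg(17)))
  for (ch in fit$chains) expect_true(all(ch$u[, 5] == 0))
  expect_gt(unname(fitted(fit)[5]), 0)
})

test_that("Gelman-Rubin separates mixed from unmixed chains", {
  set.seed(20)
  same <- list(rnorm(10000), rnorm(10000))
  expect_lt(gelman_rubin(same), 1.05)
  apart <- list(rnorm(1000, 0), rnorm(1000, 100))
  expect_gt(gelman_rubin(apart), 5)
  expect_true(is.na(gelman_rubin(list(rep(1, 100), rep(1, 100)))))
  expect_error(gelman_rubin(list(rnorm(100))), "2 chains")
})

test_that("posterior summaries follow their definitions", {
  adj <- lattice_adjacency(3, 3)
  E <- rep(25, 9)
  set.seed(22)
  Y <- rpois(9, E)
  fit <- fit_bym(Y, E, adj, quick_cfg(23))
  s <- summarize_posterior(fit)
  th <- do.call(rbind, lapply(fit$chains, function(ch)
    exp(ch$alpha + ch$u + ch$v)))
  expect_equal(s$smoothed_sir, unname(colMeans(th)))
  expect_equal(s$exceedance, unname(colMeans(th > 1)))
  expect_true(all(s$cri_low <= s$cri_high))
  expect_true(all(s$exceedance >= 0 & s$exceedance <= 1))
})

test_that("spatial fraction hits its degenerate limits", {
  mk_fit <- function(u, v) {
    structure(list(chains = list(list(
      alpha = rep(0, nrow(u)), sigma_u = rep(1, nrow(u)),
      sigma_v = rep(1, nrow(u)), u = u, v = v)),
      Y = rep(1L, ncol(u)), E = rep(1, ncol(u)),
      ids = as.character(seq_len(ncol(u))),
      islands = rep(FALSE, ncol(u))), class = "bym_fit")
  }
  u <- matrix(rnorm(150 * 6), 150)
  z <- matrix(0, 150, 6)
  expect_equal(spatial_fraction(mk_fit(u, z))$mean, 1.0)
  expect_equal(spatial_fraction(mk_fit(z, u))$mean, 0.0)
})

test_that("model-generated data land in their credible intervals", {
  # moderate-size recovery run; the full calibration lives in the
  # acceptance suite
  adj <- lattice_adjacency(7, 7)
  cfg <- scenario_config(n_areas = 49, sigma_u = 0.3, sigma_v = 0.1)
  surf <- generate_risk_surface(adj, cfg, seed = 30)
  E <- rep(20, 49)
  set.seed(31)
  Y <- rpois(49, E * surf$theta_true)
  fit <- fit_bym(Y, E, adj, quick_cfg(32))
  s <- summarize_posterior(fit)
  cover <- mean(surf$theta_true >= s$cri_low &
                surf$theta_true <= s$cri_high)
  expect_gte(cover, 0.80)
  fr <- spatial_fraction(fit)
  expect_gte(fr$mean, 0.3)
})

test_that("model methods behave like standard fit objects", {
  adj <- lattice_adjacency(4, 4)
  E <- rep(30, 16)
  set.seed(40)
  Y <- rpois(16, E)
  fit <- fit_bym(Y, E, adj, quick_cfg(41))
  co <- coef(fit)
  expect_named(co, c("alpha", "sigma_u", "sigma_v"))
  r <- residuals(fit)
  expect_equal(unname(r),
               unname((Y - E * fitted(fit)) / sqrt(E * fitted(fit))))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(16L, 3L))
  expect_true(all(sims >= 0))
  s <- summary(fit)
  expect_s3_class(s, "summary.bym_fit")
  expect_output(print(fit), "BYM fit")
})
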