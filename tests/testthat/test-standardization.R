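test_that("pooled rates follow the definition", {
  tab <- simple_strata(c("a", "b"), c(4000, 6000), c(4, 6))
  r <- estimate_reference_rates(tab)
  expect_equal(r$rate, 0.001)
  empty <- tab[0, ]
  expect_equal(nrow(estimate_reference_rates(empty)), 0)
  bad <- simple_strata("a", 0, 3)
  expect_error(estimate_reference_rates(bad), "zero population")
})

test_that("internal standardization identity: sum(E) == sum(Y)", {
  st <- simulate_study(scenario_config(n_areas = 40, seed = 21))
  rates <- estimate_reference_rates(st$strata)
  E <- expected_counts(st$strata, rates)
  Y <- observed_counts(st$strata)
  expect_lt(abs(sum(E) - sum(Y)), 1e-9)
  risk <- standardize_study(st$strata)   # internal by default
  expect_lt(abs(sum(risk$expected) - sum(risk$observed)), 1e-9)
})

test_that("expected counts are a stratum dot product", {
  tab <- data.frame(area_id = "a", age_band = c("y", "o"), sex = "A",
                    population = c(100, 200))
  rates <- data.frame(age_band = c("y", "o"), sex = "A",
                      rate = c(0.01, 0.02))
  expect_equal(unname(expected_counts(tab, rates)), 5.0)
  rates0 <- transform(rates, rate = 0)
  expect_equal(unname(expected_counts(tab, rates0)), 0)
  expect_error(expected_counts(tab, rates[1, ]), "o")
  expect_warning(e <- expected_counts(tab, rates[1, ], strict = FALSE),
                 "imputing")
  expect_equal(unname(e), 1.0)
})

test_that("raising any stratum rate never lowers any E", {
  st <- simulate_study(scenario_config(n_areas = 20, seed = 4))
  rates <- estimate_reference_rates(st$strata)
  E0 <- expected_counts(st$strata, rates)
  for (k in seq_len(nrow(rates))) {
    rk <- rates
    rk$rate[k] <- rk$rate[k] * 1.5 + 0.001
    expect_true(all(expected_counts(st$strata, rk) >= E0 - 1e-12))
  }
})

test_that("income adjustment attenuates a confounded SIR surface", {
  adj <- lattice_adjacency(8, 8)
  ids <- adj$ids
  wins <- 0L
  for (r in 1:100) {
    inc <- generate_income(adj, spatial_correlation = 1.5,
                           seed = 3000 + r)
    pop <- data.frame(area_id = rep(ids, each = 2),
                      age_band = rep(c("y", "o"), 64), sex = "A",
                      population = 2000L)
    pop$income_quintile <- inc$quintile[match(pop$area_id, inc$area_id)]
    true_rates <- make_reference_rates(c("y", "o"), "A",
                                       n_income_quintiles = 5,
                                       base_rate = 0.01, age_factor = 2,
                                       sex_factors = 1,
                                       income_gradient = 3)
    surf <- data.frame(area_id = ids, theta_true = 1)  # no real risk
    tab <- simulate_cases(pop, true_rates, surf, seed = 4000 + r)
    # age-sex-only vs income-stratified rates, both re-estimated
    r_crude <- estimate_reference_rates(tab, by = c("age_band", "sex"))
    r_adj <- estimate_reference_rates(tab)
    sir_crude <- observed_counts(tab) /
      expected_counts(tab[names(tab) != "income_quintile"], r_crude)
    sir_adj <- observed_counts(tab) / expected_counts(tab, r_adj)
    if (sum(abs(log(sir_adj))) < sum(abs(log(sir_crude)))) wins <- wins + 1L
  }
  expect_gte(wins, 90)
})

test_that("SIR arithmetic and exclusion flags", {
  r <- compute_sir(c(a = 2L, b = 0L, c = 0L), c(1, 5, 0))
  expect_equal(r$sir[1:2], c(2, 0))
  expect_true(r$excluded[3] && is.na(r$sir[3]))
  expect_error(compute_sir(c(3L), c(0)), "E = 0")
})

test_that("exact Poisson intervals match the gamma construction", {
  ci <- sir_confidence_interval(0, 3.6889)
  expect_equal(unname(ci[1, "low"]), 0)
  expect_equal(unname(ci[1, "high"]), 1.0, tolerance = 1e-3)
  ci100 <- sir_confidence_interval(100, 100)
  expect_lt(ci100[1, "low"], 1)
  expect_gt(ci100[1, "high"], 1)
  expect_lt(ci100[1, "high"] - ci100[1, "low"], 0.5)
  # chi-square quantile oracle: qgamma(p, y) == qchisq(p, 2y)/2
  for (y in c(1, 7, 100)) {
    ci <- sir_confidence_interval(y, 10)
    expect_equal(unname(ci[1, "low"]), qchisq(0.025, 2 * y) / 2 / 10,
                 tolerance = 1e-12)
    expect_equal(unname(ci[1, "high"]),
                 qchisq(0.975, 2 * (y + 1)) / 2 / 10, tolerance = 1e-12)
  }
  expect_error(sir_confidence_interval(3, 0), "E must be")
})

test_that("interval coverage at small expected counts", {
  set.seed(31)
  y <- rpois(2000, 10)
  ci <- sir_confidence_interval(y, 10)
  cover <- mean(ci[, "low"] <= 1 & ci[, "high"] >= 1)
  expect_gte(cover, 0.93)
})

test_that("aggregate_sir combines and supports complement reference", {
  st <- simulate_study(scenario_config(n_areas = 25, seed = 13))
  risk <- standardize_study(st$strata)     # internal standardization
  all_comb <- aggregate_sir(risk, risk$area_id)
  expect_equal(all_comb$sir, 1.0, tolerance = 1e-12)
  one <- aggregate_sir(risk, risk$area_id[3])
  expect_equal(one$sir, risk$sir[3])
  expect_equal(one$ci_low, risk$ci_low[3])
  toy <- compute_sir(c(a = 100L, b = 7L), c(40, 10))
  comb <- aggregate_sir(toy, c("a", "b"))
  expect_equal(comb$sir, 107 / 50)
  expect_error(aggregate_sir(risk, character(0)), "empty")
})

test_that("area risk tables round-trip as CSV", {
  risk <- compute_sir(c(a = 3L, b = 1L), c(2, 4))
  p <- tempfile(fileext = ".csv")
  write_area_risk(risk, p)
  back <- read.csv(p)
  expect_equal(back$sir, risk$sir)
  expect_equal(back$excluded, risk$excluded)
})
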