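test_that("area totals respect the population range", {
  geo <- generate_geometry(50, seed = 2)
  cfg <- scenario_config(n_areas = 50, population_range = c(400, 700))
  pop <- generate_population(geo, cfg, seed = 3)
  totals <- tapply(pop$population, pop$area_id, sum)
  expect_true(all(totals >= 400 & totals <= 700))
  cfg10 <- scenario_config(n_areas = 50, population_range = c(10, 10))
  pop10 <- generate_population(geo, cfg10, seed = 3)
  expect_true(all(tapply(pop10$population, pop10$area_id, sum) == 10))
})

test_that("mean area total matches the uniform mean at scale", {
  cfg <- scenario_config(n_areas = 1000)
  pop <- generate_population(sprintf("a%04d", 1:1000), cfg, seed = 9)
  totals <- tapply(pop$population, pop$area_id, sum)
  se <- sqrt(((700 - 400 + 1)^2 - 1) / 12 / 1000)
  expect_lt(abs(mean(totals) - 550), 3 * se)
})

test_that("empty strata definitions are rejected", {
  cfg <- scenario_config(n_areas = 4)
  cfg$age_bands <- character(0)
  expect_error(generate_population(letters[1:4], cfg, 1), "non-empty")
})

test_that("income quintiles split areas into near-equal groups", {
  adj10 <- lattice_adjacency(2, 5)
  inc <- generate_income(adj10, seed = 1)
  expect_equal(unname(table(inc$quintile)), rep(2L, 5), ignore_attr = TRUE)
  adj331 <- lattice_adjacency(331, 1)
  inc331 <- generate_income(adj331, seed = 1)
  sizes <- table(inc331$quintile)
  expect_lte(diff(range(sizes)), 1)
  # remainder goes to the lower quintiles
  expect_equal(unname(sizes[1]), 67L, ignore_attr = TRUE)
  expect_error(generate_income(lattice_adjacency(2, 2)), "at least")
})

test_that("spatially correlated income is autocorrelated", {
  adj <- lattice_adjacency(10, 10)
  w <- row_standardized_weights(adj)
  hits <- 0L
  for (r in 1:100) {
    inc <- generate_income(adj, spatial_correlation = 0.8, seed = 1000 + r)
    if (morans_i(inc$income, w) > 0) hits <- hits + 1L
  }
  expect_gte(hits, 95)
})

test_that("risk surface limits: no variation and neutral clusters", {
  adj <- lattice_adjacency(4, 4)
  cfg0 <- scenario_config(n_areas = 16, sigma_u = 0, sigma_v = 0, alpha = 0)
  s0 <- generate_risk_surface(adj, cfg0, seed = 1)
  expect_equal(s0$theta_true, rep(1, 16))
  cfg1 <- scenario_config(n_areas = 16, cluster_spec =
    list(seed_area = "r2c2", radius = 1, multiplier = 1.0))
  cfg2 <- scenario_config(n_areas = 16)
  s1 <- generate_risk_surface(adj, cfg1, seed = 5)
  s2 <- generate_risk_surface(adj, cfg2, seed = 5)
  expect_equal(s1$theta_true, s2$theta_true)
  expect_true(any(s1$cluster_member))
})

test_that("structured component sums to zero and theta decomposes", {
  adj <- lattice_adjacency(6, 6)
  cfg <- scenario_config(n_areas = 36, sigma_u = 0.4, sigma_v = 0.2,
    alpha = -0.1, cluster_spec = list(seed_area = "r3c3", radius = 2,
                                      multiplier = 2))
  s <- generate_risk_surface(adj, cfg, seed = 8)
  expect_lt(abs(sum(s$u)), 1e-9)
  expect_equal(s$theta_true, exp(cfg$alpha + s$u + s$v))
  expect_equal(sd(s$u), 0.4, tolerance = 1e-9)
})

test_that("disconnected graphs are rejected when sigma_u > 0", {
  adj <- adjacency(letters[1:4], list(2, 1, 4, 3))
  cfg <- scenario_config(n_areas = 4, sigma_u = 0.3)
  expect_error(generate_risk_surface(adj, cfg, 1), "disconnected")
  cfg0 <- scenario_config(n_areas = 4, sigma_u = 0)
  expect_silent(generate_risk_surface(adj, cfg0, 1))
})

test_that("generator calibrates to the requested spatial fraction", {
  adj <- lattice_adjacency(10, 10)
  cfg <- scenario_config(n_areas = 100, sigma_u = 0.3, sigma_v = 0.1)
  fr <- vapply(1:200, function(r) {
    s <- generate_risk_surface(adj, cfg, seed = 2000 + r)
    var(s$u) / (var(s$u) + var(s$v))
  }, 0)
  expect_lt(abs(mean(fr) - 0.9), 0.05)
})

test_that("reference rates are monotone in age and income", {
  r <- make_reference_rates(c("young", "old"), c("F", "M"))
  for (sx in c("F", "M"))
    expect_gte(r$rate[r$age_band == "old" & r$sex == sx],
               r$rate[r$age_band == "young" & r$sex == sx])
  r1 <- make_reference_rates(n_income_quintiles = 5, income_gradient = 1)
  rates_by_q <- split(r1$rate, r1$income_quintile)
  for (q in 2:5) expect_equal(rates_by_q[[q]], rates_by_q[[1]])
  r2 <- make_reference_rates(n_income_quintiles = 5, income_gradient = 2)
  q1 <- r2[r2$income_quintile == 1, ]
  q5 <- r2[r2$income_quintile == 5, ]
  expect_equal(q1$rate / q5$rate, rep(2, nrow(q1)))
})

test_that("case simulation: null process and Poisson means", {
  ids <- sprintf("a%02d", 1:20)
  pop <- data.frame(area_id = rep(ids, each = 2),
                    age_band = rep(c("young", "old"), 20),
                    sex = "A", population = 500L)
  surf <- data.frame(area_id = ids, theta_true = rep(c(1, 2), 10))
  rates0 <- data.frame(age_band = c("young", "old"), sex = "A",
                       rate = 0)
  z <- simulate_cases(pop, rates0, surf, seed = 1)
  expect_true(all(z$cases == 0))
  rates <- data.frame(age_band = c("young", "old"), sex = "A",
                      rate = c(0.01, 0.03))
  mu_total <- sum(pop$population *
    rates$rate[match(pop$age_band, rates$age_band)] *
    surf$theta_true[match(pop$area_id, surf$area_id)])
  tot <- vapply(1:1000, function(r)
    sum(simulate_cases(pop, rates, surf, seed = 5000 + r)$cases), 0)
  se <- sqrt(mu_total / 1000)   # Poisson variance of the mean
  expect_lt(abs(mean(tot) - mu_total), 3 * se)
  expect_error(simulate_cases(pop, transform(rates, rate = -1), surf),
               "rates")
})

test_that("doubling true risk stochastically increases totals", {
  ids <- sprintf("a%02d", 1:10)
  pop <- data.frame(area_id = ids, age_band = "all", sex = "A",
                    population = 200L)
  rates <- data.frame(age_band = "all", sex = "A", rate = 0.02)
  s1 <- data.frame(area_id = ids, theta_true = 1)
  s2 <- data.frame(area_id = ids, theta_true = 2)
  wins <- 0L
  for (r in 1:200) {
    t1 <- sum(simulate_cases(pop, rates, s1, seed = 7000 + r)$cases)
    t2 <- sum(simulate_cases(pop, rates, s2, seed = 9000 + r)$cases)
    if (t2 > t1) wins <- wins + 1L
  }
  # sign test: under no effect wins ~ Binomial(200, 0.5)
  expect_gt(wins, qbinom(0.99, 200, 0.5))
})

test_that("planted multiplier is recovered by the inside/outside SIR ratio", {
  adj <- lattice_adjacency(10, 10)
  cfg <- scenario_config(n_areas = 100, sigma_u = 0.3, sigma_v = 0.1,
                         cluster_spec = list(seed_area = "r5c5",
                                             radius = 1, multiplier = 2))
  pop <- data.frame(area_id = adj$ids, age_band = "all", sex = "A",
                    population = 5000L)
  rates <- data.frame(age_band = "all", sex = "A", rate = 0.01)  # E = 50
  ratios <- vapply(1:100, function(r) {
    surf <- generate_risk_surface(adj, cfg, seed = 8000 + r)
    tab <- simulate_cases(pop, rates, surf, seed = 8500 + r)
    sir <- observed_counts(tab) / expected_counts(pop, rates)
    mean(sir[surf$cluster_member]) / mean(sir[!surf$cluster_member])
  }, 0)
  expect_lt(abs(mean(ratios) - 2), 0.2)   # within 10% of the multiplier
})

test_that("whole-study generation is seed-deterministic", {
  cfg <- scenario_config(n_areas = 30, seed = 17)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$strata, b$strata)
  expect_identical(a$truth, b$truth)
  expect_identical(a$geometry$polygons, b$geometry$polygons)
  # every area appears once per stratum
  counts <- table(a$strata$area_id)
  expect_true(all(counts == length(cfg$age_bands) * length(cfg$sexes)))
  expect_true(all(a$strata$cases <= 10 * pmax(a$strata$population, 1)))
})

test_that("study files round-trip through disk formats", {
  st <- simulate_study(scenario_config(n_areas = 12, seed = 3))
  dir <- tempfile()
  write_study(st, dir)
  gj <- read_geojson(file.path(dir, "areas.geojson"))
  expect_identical(gj$layer$ids, st$geometry$ids)
  expect_equal(gj$layer$polygons, st$geometry$polygons)
  strata <- read.csv(file.path(dir, "strata.csv"))
  expect_equal(sum(strata$cases), sum(st$strata$cases))
  cfg <- jsonlite::read_json(file.path(dir, "config.json"))
  expect_equal(cfg$n_areas, 12)
})
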