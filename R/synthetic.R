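## Synthetic study regions with the statistical structure the pipeline
## assumes: an irregular tessellation of small areas (populations of a
## few hundred, like census dissemination areas), age-sex stratified
## populations, an area-level income quintile, a log-relative-risk
## surface split into a spatially structured (intrinsic autoregressive)
## and an unstructured component, and optional planted multiplicative
## risk clusters.

# Fixed age pyramid used to split an area's total population over age
# bands (within each band the sexes split evenly).  The default bands
# get documented census-like weights; any other band set falls back to
# equal weights so the generator stays usable with custom strata.
DEFAULT_AGE_BANDS <- c("0-14", "15-44", "45-64", "65+")
DEFAULT_AGE_WEIGHTS <- c(`0-14` = 0.19, `15-44` = 0.42,
                         `45-64` = 0.26, `65+` = 0.13)

age_pyramid <- function(age_bands) {
  if (identical(age_bands, DEFAULT_AGE_BANDS)) return(DEFAULT_AGE_WEIGHTS)
  w <- rep(1 / length(age_bands), length(age_bands))
  names(w) <- age_bands
  w
}

derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + 1103 * k) %% 2147483647)
}

#' Scenario configuration for synthetic study regions
#'
#' Defaults emulate the scale of a census-dissemination-area study
#' region: 331 irregular areas of 400-700 persons each, four age bands,
#' two sexes, five neighbourhood income quintiles.
#'
#' @param n_areas number of areas.
#' @param population_range integer (min, max) persons per area.
#' @param age_bands ordered character vector of age-band labels.
#' @param sexes character vector of sex labels.
#' @param n_income_quintiles 5 for an income dimension, 0 for none.
#' @param alpha baseline log relative risk.
#' @param sigma_u marginal standard deviation of the spatially
#'   structured log-risk component.
#' @param sigma_v standard deviation of the unstructured component.
#' @param cluster_spec optional `list(seed_area =, radius =, multiplier =)`
#'   planting a multiplicative risk cluster of the given graph radius.
#' @param seed master seed for the scenario.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n_areas = 331L,
                            population_range = c(400L, 700L),
                            age_bands = DEFAULT_AGE_BANDS,
                            sexes = c("F", "M"),
                            n_income_quintiles = 5L,
                            alpha = 0,
                            sigma_u = 0.3,
                            sigma_v = 0.1,
                            cluster_spec = NULL,
                            seed = 1L) {
  if (n_areas < 1) stop("n_areas must be >= 1")
  if (length(population_range) != 2L || population_range[1] < 1 ||
      population_range[2] < population_range[1])
    stop("population_range must be (min, max) with min >= 1")
  if (!length(age_bands) || !length(sexes))
    stop("age_bands and sexes must be non-empty")
  if (sigma_u < 0 || sigma_v < 0) stop("sigma_u, sigma_v must be >= 0")
  if (!is.null(cluster_spec)) {
    stopifnot(is.list(cluster_spec),
              all(c("seed_area", "radius", "multiplier") %in%
                    names(cluster_spec)))
    if (cluster_spec$multiplier <= 0) stop("risk multiplier must be > 0")
  }
  if (n_income_quintiles != 0 && n_income_quintiles != 5)
    stop("n_income_quintiles must be 0 or 5")
  structure(list(n_areas = as.integer(n_areas),
                 population_range = as.integer(population_range),
                 age_bands = age_bands, sexes = sexes,
                 n_income_quintiles = as.integer(n_income_quintiles),
                 alpha = alpha, sigma_u = sigma_u, sigma_v = sigma_v,
                 cluster_spec = cluster_spec, seed = as.integer(seed)),
            class = "scenario_config")
}

#' Generate stratified area populations
#'
#' Each area's total is drawn uniformly (inclusive) from
#' `population_range`, then split over age x sex strata by a single
#' multinomial draw with the fixed age-pyramid weights, so totals are
#' preserved exactly.
#'
#' @param layer an `area_polygons` object (supplies the area IDs).
#' @param config a [scenario_config()].
#' @param seed integer seed.
#' @return A data.frame (stratum table, population part) with columns
#'   `area_id`, `age_band`, `sex`, `population`.
#' @export
generate_population <- function(layer, config, seed = NULL) {
  ids <- if (inherits(layer, "area_polygons")) layer$ids
         else as.character(layer)
  if (!length(config$age_bands) || !length(config$sexes))
    stop("age_bands and sexes must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  aw <- age_pyramid(config$age_bands)
  pr <- outer(aw / length(config$sexes),
              rep(1, length(config$sexes)))  # bands x sexes
  pvec <- as.vector(pr)
  lo <- config$population_range[1]; hi <- config$population_range[2]
  totals <- if (lo == hi) rep(lo, length(ids))
            else sample(lo:hi, length(ids), replace = TRUE)
  grid <- expand.grid(age_band = config$age_bands, sex = config$sexes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    cnt <- as.vector(rmultinom(1, totals[i], pvec))
    out[[i]] <- data.frame(area_id = ids[i], grid,
                           population = cnt, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Generate area incomes and quintile labels
#'
#' A continuous area income with optional positive neighbour correlation
#' (a one-step spatial moving average over the adjacency graph), then a
#' rank-based split into 5 near-equal quintile groups, remainder going
#' to the lower quintiles, ties broken by area ID order.  Quintile 1 is
#' the lowest income.
#'
#' @param adj an `adjacency` object.
#' @param spatial_correlation weight (>= 0) on the neighbourhood average
#'   in the moving-average mix; 0 gives independent incomes.
#' @param seed integer seed.
#' @param n_quintiles number of quantile groups (default 5).
#' @return data.frame with `area_id`, `income`, `quintile`.
#' @export
generate_income <- function(adj, spatial_correlation = 0.8, seed = NULL,
                            n_quintiles = 5L) {
  stopifnot(inherits(adj, "adjacency"))
  n <- length(adj$ids)
  if (n < n_quintiles)
    stop("need at least ", n_quintiles, " areas for ", n_quintiles,
         " quintiles")
  if (!is.null(seed)) set.seed(seed)
  e <- rnorm(n)
  avg <- vapply(seq_len(n), function(i) {
    nbs <- adj$neighbours[[i]]
    if (length(nbs)) mean(e[nbs]) else 0
  }, 0)
  income <- e + spatial_correlation * avg
  # rank split: sizes differ by at most one, remainder to lower quintiles
  base <- n %/% n_quintiles
  sizes <- base + as.integer(seq_len(n_quintiles) <= n %% n_quintiles)
  ord <- order(income, adj$ids)
  quintile <- integer(n)
  quintile[ord] <- rep(seq_len(n_quintiles), times = sizes)
  data.frame(area_id = adj$ids, income = income, quintile = quintile,
             stringsAsFactors = FALSE)
}

# Sample the intrinsic autoregressive (ICAR) distribution on a connected
# graph: eigen-decompose the graph Laplacian, drop the null direction,
# draw independent normals with variance 1/eigenvalue along the
# remaining eigenvectors, then rescale so the empirical (n-1 denominator)
# standard deviation equals sigma_u.  The intrinsic prior is improper,
# so the scale convention must be fixed explicitly; the empirical-sd
# convention makes the generator's marginal spread exactly sigma_u.
sample_icar <- function(adj, sigma_u) {
  n <- length(adj$ids)
  if (n < 2L) stop("ICAR sampling needs at least 2 connected areas")
  deg <- lengths(adj$neighbours)
  L <- diag(deg)
  for (i in seq_len(n)) L[i, adj$neighbours[[i]]] <- -1
  eig <- eigen(L, symmetric = TRUE)
  pos <- eig$values > 1e-8 * max(eig$values)
  z <- rnorm(sum(pos))
  x <- eig$vectors[, pos, drop = FALSE] %*% (z / sqrt(eig$values[pos]))
  x <- as.vector(x)
  x <- x - mean(x)
  s <- sd(x)
  if (s == 0) return(rep(0, n))
  x * (sigma_u / s)
}

#' Generate a true relative-risk surface
#'
#' Per-area log relative risk alpha + u + v, with `u` an intrinsic
#' autoregressive (spatially smooth) component scaled to empirical
#' standard deviation `sigma_u` and sum zero, and `v` independent
#' Normal(0, sigma_v).  An optional planted cluster multiplies the risk
#' of all areas within `radius` graph steps of the seed area by
#' `multiplier`; the multiplier is carried in `v` so that
#' `theta_true == exp(alpha + u + v)` holds exactly everywhere.
#'
#' @param adj an `adjacency` object; must be connected when
#'   `sigma_u > 0`.
#' @param config a [scenario_config()].
#' @param seed integer seed.
#' @return A data.frame (`true_risk_surface`) with columns `area_id`,
#'   `theta_true`, `u`, `v`, `cluster_member`.
#' @export
generate_risk_surface <- function(adj, config, seed = NULL) {
  stopifnot(inherits(adj, "adjacency"))
  n <- length(adj$ids)
  if (!is.null(seed)) set.seed(seed)
  if (config$sigma_u > 0) {
    comp <- graph_components(adj)
    if (max(comp) > 1L) {
      sizes <- table(comp)
      stop("adjacency graph is disconnected (components of sizes ",
           paste(sizes, collapse = ", "),
           "); sigma_u > 0 requires a connected graph")
    }
    u <- sample_icar(adj, config$sigma_u)
  } else {
    u <- rep(0, n)
  }
  v <- if (config$sigma_v > 0) rnorm(n, 0, config$sigma_v) else rep(0, n)
  cluster_member <- rep(FALSE, n)
  cs <- config$cluster_spec
  if (!is.null(cs)) {
    d <- graph_distance(adj, cs$seed_area)
    cluster_member <- d <= cs$radius
    v[cluster_member] <- v[cluster_member] + log(cs$multiplier)
  }
  theta <- exp(config$alpha + u + v)
  structure(data.frame(area_id = adj$ids, theta_true = theta, u = u,
                       v = v, cluster_member = cluster_member,
                       stringsAsFactors = FALSE),
            class = c("true_risk_surface", "data.frame"))
}

#' Construct reference stratum rates
#'
#' Builds a plausible rate vector over age x sex (x income quintile)
#' strata: rates rise geometrically with age band within each sex, an
#' optional male:female ratio, and an optional monotone income gradient
#' for confounding scenarios (`income_gradient` is the exact ratio of
#' the quintile-1 rate to the quintile-5 rate within every age-sex
#' stratum).
#'
#' @param age_bands ordered age-band labels (youngest first).
#' @param sexes sex labels; the rate multiplier in `sex_factors` is
#'   matched by position (default: second sex 20% higher).
#' @param n_income_quintiles 0 (no income dimension) or 5.
#' @param base_rate rate (cases per person per study period) in the
#'   youngest band of the first sex.
#' @param age_factor multiplicative increase per successive age band
#'   (>= 1 keeps rates monotone in age).
#' @param sex_factors multipliers per sex, recycled.
#' @param income_gradient quintile-1 / quintile-5 rate ratio (1 = none).
#' @return A data.frame rate vector: `age_band`, `sex`,
#'   (`income_quintile`,) `rate`.
#' @export
make_reference_rates <- function(age_bands = DEFAULT_AGE_BANDS,
                                 sexes = c("F", "M"),
                                 n_income_quintiles = 0L,
                                 base_rate = 0.002,
                                 age_factor = 2.5,
                                 sex_factors = c(1, 1.2),
                                 income_gradient = 1) {
  if (!length(age_bands) || !length(sexes))
    stop("strata definition must be non-empty")
  if (age_factor < 1) stop("age_factor must be >= 1 (monotone rates)")
  sex_factors <- rep_len(sex_factors, length(sexes))
  g <- expand.grid(age_band = age_bands, sex = sexes,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ai <- match(g$age_band, age_bands)
  si <- match(g$sex, sexes)
  g$rate <- base_rate * age_factor^(ai - 1) * sex_factors[si]
  if (n_income_quintiles > 0) {
    qs <- seq_len(n_income_quintiles)
    g <- do.call(rbind, lapply(qs, function(q) {
      gg <- g
      gg$income_quintile <- q
      gg$rate <- gg$rate *
        income_gradient^((n_income_quintiles - q) / (n_income_quintiles - 1))
      gg
    }))
    g <- g[, c("age_band", "sex", "income_quintile", "rate")]
  }
  rownames(g) <- NULL
  g
}

#' Simulate stratum case counts
#'
#' Case counts are Poisson with mean persons x stratum reference rate x
#' the area's true relative risk.
#'
#' @param pop_table population stratum table from
#'   [generate_population()], optionally carrying an `income_quintile`
#'   column.
#' @param rates rate vector from [make_reference_rates()] (or any
#'   data.frame keyed the same way).
#' @param surface a `true_risk_surface` (or a data.frame with `area_id`
#'   and `theta_true`).
#' @param seed integer seed.
#' @return The stratum table with a `cases` column appended.
#' @export
simulate_cases <- function(pop_table, rates, surface, seed = NULL) {
  if (any(!is.finite(rates$rate)) || any(rates$rate < 0))
    stop("rates must be finite and >= 0")
  if (!is.null(seed)) set.seed(seed)
  r <- match_stratum_rates(pop_table, rates)
  th <- surface$theta_true[match(pop_table$area_id, surface$area_id)]
  if (anyNA(th)) stop("risk surface missing areas present in the table")
  mu <- pop_table$population * r * th
  out <- pop_table
  out$cases <- rpois(nrow(out), mu)
  out
}

# look up each table row's rate; rates may or may not carry an income
# dimension independently of the table
match_stratum_rates <- function(tab, rates, strict = TRUE) {
  has_q <- "income_quintile" %in% names(rates)
  key_t <- if (has_q) {
    if (!"income_quintile" %in% names(tab))
      stop("rates are income-stratified but the table has no ",
           "income_quintile column")
    paste(tab$age_band, tab$sex, tab$income_quintile)
  } else paste(tab$age_band, tab$sex)
  key_r <- if (has_q) paste(rates$age_band, rates$sex, rates$income_quintile)
           else paste(rates$age_band, rates$sex)
  idx <- match(key_t, key_r)
  if (anyNA(idx)) {
    missing_keys <- unique(key_t[is.na(idx)])
    if (strict) stop("no reference rate for stratum: ",
                     paste(missing_keys, collapse = "; "))
    warning("imputing rate 0 for strata: ",
            paste(missing_keys, collapse = "; "))
    r <- rates$rate[idx]
    r[is.na(r)] <- 0
    return(r)
  }
  rates$rate[idx]
}

#' Simulate a complete synthetic study
#'
#' Orchestrates geometry, adjacency, population, income, risk surface
#' and case simulation under one master seed (sub-seeds are derived
#' deterministically per stage).
#'
#' @param config a [scenario_config()].
#' @return A `synthetic_study` list: `geometry`, `adjacency`, `strata`
#'   (stratum table with cases), `truth`, `rates`, `income`, `config`.
#' @examples
#' st <- simulate_study(scenario_config(n_areas = 40, seed = 7))
#' head(st$strata)
#' @export
simulate_study <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  geo <- generate_geometry(config$n_areas, derive_seed(config$seed, 1))
  adj <- build_adjacency(geo, "queen")
  pop <- generate_population(geo, config, derive_seed(config$seed, 2))
  income <- NULL
  if (config$n_income_quintiles > 0 && config$n_areas >= 5) {
    income <- generate_income(adj, spatial_correlation = 0.8,
                              seed = derive_seed(config$seed, 3))
    pop$income_quintile <- income$quintile[match(pop$area_id,
                                                 income$area_id)]
  }
  truth <- generate_risk_surface(adj, config, derive_seed(config$seed, 4))
  rates <- make_reference_rates(config$age_bands, config$sexes)
  strata <- simulate_cases(pop, rates, truth, derive_seed(config$seed, 5))
  structure(list(geometry = geo, adjacency = adj, strata = strata,
                 truth = truth, rates = rates, income = income,
                 config = config),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_study: %d areas, %d strata rows, ",
                     "%d cases, seed %d>\n"),
              x$config$n_areas, nrow(x$strata), sum(x$strata$cases),
              x$config$seed))
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' GeoJSON polygons, strata CSV (`area_id, age_band, sex,
#' income_quintile, population, cases`), truth CSV (`area_id,
#' theta_true, u, v, cluster_member`) and a JSON echo of the
#' configuration.
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_geojson(study$geometry, file.path(dir, "areas.geojson"))
  st <- study$strata
  if (!"income_quintile" %in% names(st)) st$income_quintile <- NA
  st <- st[, c("area_id", "age_band", "sex", "income_quintile",
               "population", "cases")]
  write.csv(st, file.path(dir, "strata.csv"), row.names = FALSE)
  write.csv(study$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  cfg <- study$config
  cfg$cluster_spec <- if (is.null(cfg$cluster_spec)) NULL
                      else cfg$cluster_spec
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
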