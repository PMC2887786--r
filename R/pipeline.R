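## End-to-end orchestration mirroring the analysis stage order:
## standardize -> Moran screen -> BYM smoothing on flagged outcomes ->
## scan corroboration -> classified map layers.  One master seed
## propagates deterministic sub-seeds to every stochastic stage.

#' Pipeline configuration
#'
#' @param scenario a [scenario_config()] (used when simulating) or
#'   `NULL` when a study is supplied to [run_pipeline()] directly.
#' @param screen_B bootstrap replicates for the Moran screen.
#' @param screen_alpha family-wise error level of the screen.
#' @param screen_m Bonferroni family size (`NULL`: number of outcomes).
#' @param mcmc an [mcmc_config()].
#' @param scan_max_fraction zone cap for the scan.
#' @param scan_n_sim scan null replicates.
#' @param breaks a [class_scheme()].
#' @param exceedance_threshold flag cut for exceedance overlays.
#' @param seed master seed.
#' @param out_dir optional output directory; when given, stage outputs
#'   (CSV/GeoJSON/JSON) are written there.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(scenario = scenario_config(),
                            screen_B = 999L, screen_alpha = 0.05,
                            screen_m = NULL,
                            mcmc = mcmc_config(),
                            scan_max_fraction = 0.5,
                            scan_n_sim = 999L,
                            breaks = class_scheme(),
                            exceedance_threshold = 0.80,
                            seed = 1L, out_dir = NULL) {
  structure(list(scenario = scenario, screen_B = as.integer(screen_B),
                 screen_alpha = screen_alpha, screen_m = screen_m,
                 mcmc = mcmc,
                 scan_max_fraction = scan_max_fraction,
                 scan_n_sim = as.integer(scan_n_sim), breaks = breaks,
                 exceedance_threshold = exceedance_threshold,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full small-area risk-mapping pipeline
#'
#' Simulates (or accepts) a study, indirectly standardizes it, screens
#' the SIR surface for spatial autocorrelation with the parametric
#' bootstrap Moran test under Bonferroni control, fits the BYM model to
#' flagged outcomes only, corroborates with the Poisson spatial scan,
#' and assembles classified map records.  Unpopulated areas (E = 0)
#' are excluded from the spatial stages but retained, flagged, in the
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @param study optional `synthetic_study` (otherwise simulated from
#'   `config$scenario`).
#' @return A `pipeline_run` list with elements `risk` (area risk
#'   table), `screen`, `bym` (fit or `NULL`), `posterior`, `scan`,
#'   `maps`, `report`.
#' @export
run_pipeline <- function(config = pipeline_config(), study = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  if (is.null(study)) {
    sc <- config$scenario
    sc$seed <- derive_seed(config$seed, 11)
    study <- simulate_study(sc)
  }
  adj <- study$adjacency
  risk <- standardize_study(study$strata, study$rates)
  keep <- !risk$excluded

  ## Moran screen on the SIR surface
  w <- row_standardized_weights(adj)
  mres <- parametric_bootstrap_p(
    replace(rep(0L, nrow(risk)), which(keep), risk$observed[keep]),
    replace(rep(0, nrow(risk)), which(keep), risk$expected[keep]),
    w, B = config$screen_B, seed = derive_seed(config$seed, 12))
  screen <- bonferroni_screen(
    data.frame(site = "outcome", moran_i = mres$statistic,
               p_value = mres$p_value, B = mres$B),
    alpha = config$screen_alpha,
    m = if (is.null(config$screen_m)) 1L else config$screen_m)

  ## BYM smoothing on flagged outcomes only
  fit <- NULL; post <- NULL; frac <- NULL; rhat <- NULL
  if (any(screen$flagged)) {
    sub_adj <- subset_adjacency(adj, which(keep))
    cfg <- config$mcmc
    cfg$seed <- derive_seed(config$seed, 13)
    fit <- fit_bym(risk$observed[keep], risk$expected[keep], sub_adj, cfg)
    post <- summarize_posterior(fit)
    frac <- spatial_fraction(fit)
    rhat <- if (length(fit$chains) >= 2L)
      gelman_rubin(fit, c("alpha", "sigma_u", "sigma_v", "theta"))
    else NULL
    if (!is.null(rhat) && any(rhat >= 1.1, na.rm = TRUE))
      warning("convergence gate: some monitored R-hat >= 1.1")
  }

  ## scan corroboration
  scan <- NULL
  if (any(screen$flagged)) {
    cen <- area_centroids(study$geometry)[keep, , drop = FALSE]
    scan <- monte_carlo_scan(risk$observed[keep], risk$expected[keep],
                             cen, config$scan_max_fraction,
                             config$scan_n_sim,
                             seed = derive_seed(config$seed, 14),
                             ids = risk$area_id[keep])
  }

  ## map records: raw always; smoothed when fitted
  sig_raw <- !is.na(risk$ci_low) & (risk$ci_low > 1 | risk$ci_high < 1)
  maps <- list(raw = map_records(risk$area_id, risk$sir, config$breaks,
                                 significant = sig_raw))
  if (!is.null(post)) {
    ex <- exceedance_flags(post$exceedance, config$exceedance_threshold)
    sm <- rep(NA_real_, nrow(risk))
    exf <- rep(NA, nrow(risk))
    sm[keep] <- post$smoothed_sir
    exf[keep] <- ex
    maps$smoothed <- map_records(risk$area_id, sm, config$breaks,
                                 exceedance = exf)
  }

  report <- list(
    seed = config$seed,
    n_areas = nrow(risk), n_excluded = sum(!keep),
    total_observed = sum(risk$observed),
    total_expected = sum(risk$expected),
    moran_i = mres$statistic, moran_p = mres$p_value,
    screen_flagged = any(screen$flagged),
    spatial_fraction = if (is.null(frac)) NULL else
      frac[c("mean", "ci_low", "ci_high")],
    max_rhat = if (is.null(rhat)) NULL else max(rhat, na.rm = TRUE),
    scan_p = if (is.null(scan)) NULL else scan$p_value,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  run <- structure(list(study = study, risk = risk, screen = screen,
                        bym = fit, posterior = post,
                        spatial_fraction = frac, scan = scan,
                        maps = maps, report = report, config = config),
                   class = "pipeline_run")
  if (!is.null(config$out_dir)) write_pipeline_outputs(run)
  run
}

# restrict an adjacency to a subset of area indices
subset_adjacency <- function(adj, idx) {
  map <- match(seq_along(adj$ids), idx)
  nb <- lapply(idx, function(i) {
    m <- map[adj$neighbours[[i]]]
    sort(m[!is.na(m)])
  })
  new_adjacency(adj$ids[idx], nb)
}

#' @export
print.pipeline_run <- function(x, ...) {
  r <- x$report
  cat(sprintf("pipeline run (seed %d): %d areas, %d cases\n",
              r$seed, r$n_areas, r$total_observed))
  cat(sprintf("  Moran's I = %.3f (p = %.4g), screen %s\n", r$moran_i,
              r$moran_p,
              if (r$screen_flagged) "flagged" else "not flagged"))
  if (!is.null(r$spatial_fraction))
    cat(sprintf("  spatial fraction %.2f, scan p = %.4g\n",
                r$spatial_fraction$mean, r$scan_p))
  invisible(x)
}

write_pipeline_outputs <- function(run) {
  dir <- run$config$out_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_area_risk(run$risk, file.path(dir, "area_risk.csv"))
  write.csv(as.data.frame(run$screen), file.path(dir, "screen.csv"),
            row.names = FALSE)
  if (!is.null(run$posterior))
    write.csv(run$posterior, file.path(dir, "posterior.csv"),
              row.names = FALSE)
  if (!is.null(run$scan))
    write_scan_report(run$scan, file.path(dir, "scan.json"))
  write_map_layer(run$study$geometry, run$maps$raw,
                  file.path(dir, "map_raw.geojson"))
  if (!is.null(run$maps$smoothed))
    write_map_layer(run$study$geometry, run$maps$smoothed,
                    file.path(dir, "map_smoothed.geojson"))
  jsonlite::write_json(run$report, file.path(dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
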