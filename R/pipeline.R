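#' Default end-to-end experiment configuration
#'
#' Assembles the configuration of the full synthetic experiment: the four
#' packaged sites, per-stage seeds (derived from one base seed so stages can
#' be rerun independently), the simulated-station settings, the ensemble
#' size, the ground-truth abundance model, and the extra-site grid used for
#' spatial validation.
#'
#' @param seed Base integer seed; per-stage seeds are small offsets of it.
#' @param n_years Simulated years per station/microclimate ensemble.
#' @param n_replicates Replicate counts per site x month.
#' @param n_extra_sites Number of extra sites on the 2600-3600 m elevation
#'   gradient used for spatial validation.
#' @param true_coefs Ground-truth abundance model (candidate-term names; see
#'   [simulate_abundances()]), applied to the microclimate summaries.
#' @param abundance_noise_sd Count-scale noise SD of the generator.
#' @param elevation_error_gain Multiplier by which extra-site abundance
#'   noise grows per km of elevation above 2600 m (creates the
#'   error-vs-elevation gradient probed by [spatial_validation()]).
#' @param station Settings of the simulated 3-year logger record.
#' @param output_dir Where [run_experiment()] writes its artifacts
#'   (default: a fresh temporary directory).
#' @param make_plots Write diagnostic plot files (needs ggplot2).
#' @return A `run_config` list.
#' @export
default_run_config <- function(seed = 42, n_years = 30, n_replicates = 6,
                               n_extra_sites = 15,
                               true_coefs = c(intercept = 20, S = 150,
                                              q3F = 0.5),
                               abundance_noise_sd = 15,
                               elevation_error_gain = 2,
                               station = list(trend_slope = 0.02,
                                              noise_sd = 0.8,
                                              monthly_anomaly_sd = 0.5,
                                              n_years = 3),
                               output_dir = NULL, make_plots = FALSE) {
  structure(
    list(sites = site_specs(),
         seeds = list(station = seed + 1L, landscape = seed + 101L,
                      ensemble = seed + 201L, abundance = seed + 301L,
                      spatial = seed + 401L),
         n_years = n_years, n_replicates = n_replicates,
         n_extra_sites = n_extra_sites, true_coefs = true_coefs,
         abundance_noise_sd = abundance_noise_sd,
         elevation_error_gain = elevation_error_gain,
         station = station, species = species_params(),
         canopy = canopy_models(), rotation = default_rotation(),
         output_dir = output_dir, make_plots = make_plots),
    class = "run_config"
  )
}

# synthetic extra-site grid for spatial validation: a lapse rate of
# -0.0056 degC/m anchored at the lowest monitored site
extra_site_specs <- function(n, seed) {
  elev <- seq(2600, 3600, length.out = n)
  set.seed(seed)
  n_fields <- sample(40:84, n, replace = TRUE)
  lapply(seq_len(n), function(k) {
    site_spec(site_code = sprintf("Extra %02d", k), elevation = elev[k],
              n_fields = n_fields[k],
              mean_annual_temp = 13.3 - 0.0056 * (elev[k] - 2713),
              intra_annual_sd = 0.55)
  })
}

# the three standardized ensembles for one site, given a fitted (or assumed)
# random-component model
site_ensembles <- function(spec, rcm, config, site_index) {
  wc <- make_worldclim_fixture(spec)
  st <- simulate_station_ensemble(wc, rcm, config$n_years,
                                  seed = config$seeds$ensemble + site_index)
  land <- simulate_landscape(spec, seed = config$seeds$landscape + site_index)
  mc <- build_microclimate_ensemble(st, land, config$canopy, config$rotation)
  list(worldclim = wc, station = st, microclimate = mc)
}

# bind per-site summaries, keeping the shared provenance attribute
bind_summaries <- function(lst) {
  out <- dplyr::bind_rows(lst)
  attr(out, "provenance") <- attr(lst[[1]], "provenance")
  out
}

#' Run the full synthetic experiment end-to-end
#'
#' For each of the four packaged sites: builds the climatology ensemble,
#' simulates and standardizes a 3-year station record (monthly aggregation,
#' classical decomposition, lag-0 cross-correlation of seasonality against
#' the climatology, Gaussian fit to the random component), simulates the
#' station ensemble and the landscape-level microclimate ensemble, and
#' summarizes pest performance over each of the three ensembles. Abundances
#' are then generated from the configured ground-truth model, the three
#' dataset-specific stepwise-AIC regressions are fitted and validated
#' temporally, and spatial validation is run on a synthetic elevation
#' gradient of extra sites. All artifacts are written under
#' `config$output_dir`; the manifest (also returned) records the config
#' hash, seeds, and every fitted quantity.
#'
#' @param config A [default_run_config()].
#' @return The run manifest, invisibly (a list; also written as
#'   `summary.json`).
#' @export
run_experiment <- function(config = default_run_config()) {
  out_dir <- config$output_dir %||% file.path(tempfile("pestclim_run_"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "ensembles"), showWarnings = FALSE)

  sites <- config$sites
  per_site <- list()
  summaries <- list(worldclim = list(), station = list(),
                    microclimate = list())

  for (i in seq_along(sites)) {
    spec <- sites[[i]]
    wc <- make_worldclim_fixture(spec)
    series <- simulate_station_series(
      seasonal = ensemble_monthly_values(wc),
      trend_slope = config$station$trend_slope,
      noise_sd = config$station$noise_sd,
      monthly_anomaly_sd = config$station$monthly_anomaly_sd,
      n_years = config$station$n_years, resolution_minutes = 30,
      seed = config$seeds$station + i, site_code = spec$site_code)
    monthly <- aggregate_to_monthly(series)
    dec <- decompose_monthly(monthly)
    wc_values <- ensemble_monthly_values(wc)
    ccf0 <- cross_correlation_lag0(wc_values - mean(wc_values), dec$seasonal)
    rcm <- detrend_and_fit_random(monthly)

    ens <- site_ensembles(spec, rcm, config, i)
    for (ds in names(ens)) {
      summaries[[ds]][[spec$site_code]] <-
        summarize_performance(ens[[ds]], config$species)
      utils::write.csv(
        as.data.frame(ens[[ds]]),
        file.path(out_dir, "ensembles",
                  sprintf("%s_%s.csv", gsub("\\s+", "", spec$site_code), ds)),
        row.names = FALSE)
    }
    per_site[[spec$site_code]] <- list(
      elevation = spec$elevation, ccf_lag0 = ccf0,
      random_component = list(mu = rcm$mu, sigma = rcm$sigma,
                              shapiro_w = rcm$shapiro_w,
                              shapiro_p = rcm$shapiro_p))
  }

  summaries <- lapply(summaries, bind_summaries)
  for (ds in names(summaries)) {
    utils::write.csv(as.data.frame(summaries[[ds]]),
                     file.path(out_dir, sprintf("summaries_%s.csv", ds)),
                     row.names = FALSE)
  }

  # ground-truth abundances are driven by the microclimate-scale summaries
  abundances <- simulate_abundances(
    summaries$microclimate, config$true_coefs,
    noise_sd = config$abundance_noise_sd,
    n_replicates = config$n_replicates, seed = config$seeds$abundance)
  utils::write.csv(as.data.frame(abundances),
                   file.path(out_dir, "abundances.csv"), row.names = FALSE)

  models <- lapply(summaries, function(sm) {
    stepwise_aic(build_design_matrix(sm, abundances))
  })
  writeLines(utils::capture.output(print(as.data.frame(fit_report(models)))),
             file.path(out_dir, "fit_report.txt"))

  temporal <- lapply(names(models), function(ds) {
    dm <- build_design_matrix(summaries[[ds]], abundances)
    pred <- predict(models[[ds]]$fit, newdata = dm)
    temporal_validation(dm$count, unname(pred), model = models[[ds]])
  })
  names(temporal) <- names(models)

  # spatial validation on a synthetic elevation gradient; extra sites reuse
  # the pooled random-component model (extrapolation, as at unmonitored
  # sites), and their abundance noise grows with elevation
  mu_bar <- mean(vapply(per_site, function(s) s$random_component$mu, 0))
  sigma_bar <- mean(vapply(per_site, function(s) s$random_component$sigma, 0))
  rcm_bar <- list(mu = mu_bar, sigma = sigma_bar)
  extras <- extra_site_specs(config$n_extra_sites, config$seeds$spatial)
  extra_summ <- list(worldclim = list(), station = list(),
                     microclimate = list())
  extra_abund <- list()
  for (k in seq_along(extras)) {
    spec <- extras[[k]]
    ens <- site_ensembles(spec, rcm_bar, config, 1000L + k)
    for (ds in names(ens)) {
      extra_summ[[ds]][[spec$site_code]] <-
        summarize_performance(ens[[ds]], config$species)
    }
    # site-level departure from the fitted model, growing with elevation:
    # replicate-level noise averages out of site means, so the
    # error-vs-elevation gradient must live at the site level
    gain <- 1 + config$elevation_error_gain * (spec$elevation - 2600) / 1000
    set.seed(config$seeds$spatial + 10L * k + 1L)
    site_offset <- rnorm(1, 0, config$abundance_noise_sd * gain)
    tc <- unlist(config$true_coefs)
    if (!"intercept" %in% names(tc)) tc <- c(intercept = 0, tc)
    tc["intercept"] <- tc[["intercept"]] + site_offset
    extra_abund[[k]] <- simulate_abundances(
      extra_summ$microclimate[[spec$site_code]], tc,
      noise_sd = config$abundance_noise_sd,
      n_replicates = config$n_replicates,
      seed = config$seeds$spatial + 10L * k)
  }
  extra_summ <- lapply(extra_summ, bind_summaries)
  extra_abund <- dplyr::bind_rows(extra_abund)
  elevs <- tibble(site = vapply(extras, function(s) s$site_code, ""),
                  elevation = vapply(extras, function(s) s$elevation, 0))
  spatial <- spatial_validation(models, extra_summ, extra_abund, elevs)

  manifest <- list(
    package = "pestclim",
    config_hash = rlang::hash(config[setdiff(names(config),
                                             c("output_dir", "make_plots"))]),
    seeds = config$seeds,
    n_years = config$n_years,
    n_replicates = config$n_replicates,
    sites = per_site,
    models = lapply(models, function(m) {
      list(terms = m$selected_terms, coefficients = as.list(m$coefficients),
           aic = m$aic, r_squared = m$r_squared, n_obs = m$n_obs)
    }),
    temporal_validation = temporal,
    spatial_validation = lapply(split(spatial, spatial$dataset), as.list),
    outputs = list(  # paths relative to the run directory
      ensembles = "ensembles",
      abundances = "abundances.csv",
      fit_report = "fit_report.txt")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  if (isTRUE(config$make_plots) &&
      requireNamespace("ggplot2", quietly = TRUE)) {
    save_run_plots(out_dir, summaries, models, abundances)
  }
  manifest$output_dir <- out_dir
  invisible(manifest)
}

# Figure-style diagnostics: monthly performance summaries per dataset and
# observed-vs-predicted abundances; optional artifacts, never load-bearing
save_run_plots <- function(out_dir, summaries, models, abundances) {
  df <- dplyr::bind_rows(lapply(names(summaries), function(ds) {
    dplyr::mutate(summaries[[ds]], dataset = ds)
  }))
  p1 <- ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$month),
                                         y = .data$temp_mean,
                                         colour = .data$dataset)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~site) +
    ggplot2::labs(x = "month", y = "mean temperature (degC)")
  ggplot2::ggsave(file.path(out_dir, "monthly_temperatures.png"), p1,
                  width = 8, height = 6, dpi = 120)
  obs <- dplyr::summarise(dplyr::group_by(abundances, .data$site, .data$month),
                          observed = mean(.data$count), .groups = "drop")
  pr <- dplyr::bind_rows(lapply(names(models), function(ds) {
    dplyr::mutate(predict_abundance(models[[ds]], summaries[[ds]]),
                  dataset = ds)
  }))
  d <- dplyr::inner_join(obs, pr, by = c("site", "month"))
  p2 <- ggplot2::ggplot(d, ggplot2::aes(x = .data$observed,
                                        y = .data$predicted,
                                        colour = .data$dataset)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "observed abundance", y = "predicted abundance")
  ggplot2::ggsave(file.path(out_dir, "observed_vs_predicted.png"), p2,
                  width = 7, height = 5, dpi = 120)
  invisible(NULL)
}
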