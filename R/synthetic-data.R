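#' Monthly climatology fixture for a site
#'
#' Builds the 12 monthly reference temperatures for a site from its annual
#' mean and intra-annual standard deviation, emulating a 50-year interpolated
#' climatology. A fixed cosine seasonal shape peaking in February (the warm
#' season runs roughly November-May at these equatorial Andean sites) is
#' rescaled so that the mean of the 12 values equals `mean_annual_temp` and
#' their standard deviation equals `intra_annual_sd` exactly.
#'
#' @param site A [site_spec()] or a packaged site code.
#' @param seed Unused (the construction is deterministic); accepted so all
#'   generators share one calling convention.
#' @return A [monthly_ensemble()] with provenance `"worldclim"` (one value
#'   per month).
#' @export
make_worldclim_fixture <- function(site, seed = NULL) {
  site <- get_site_spec(site)
  shape <- cos(2 * pi * (1:12 - 2) / 12)
  if (site$intra_annual_sd == 0) {
    values <- rep(site$mean_annual_temp, 12L)
  } else {
    values <- site$mean_annual_temp +
      site$intra_annual_sd * (shape - mean(shape)) / sd(shape)
  }
  monthly_ensemble(tibble(month = 1:12, value = values),
                   site_code = site$site_code, provenance = "worldclim")
}

#' Simulate a weather-station logger series
#'
#' Generates a timestamped air-temperature series with additive structure
#' `value(t) = seasonal[month(t)] + trend_slope * years_elapsed(t) +
#' diurnal(t) + anomaly(month) + N(0, noise_sd)`, emulating a data logger
#' recording every 30 (or 1) minutes. The diurnal term is a sinusoid peaking
#' at 15:00 local time. `monthly_anomaly_sd` adds a month-scale weather
#' anomaly shared by all readings within a calendar month; without it,
#' reading-level noise averages out of monthly means almost completely.
#'
#' @param seasonal 12 monthly baseline temperatures (deg C, Jan..Dec).
#' @param trend_slope Linear trend in deg C per year.
#' @param noise_sd Reading-level Gaussian noise SD (deg C, >= 0).
#' @param n_years Number of calendar years to simulate (>= 1).
#' @param resolution_minutes Logger interval: 1 or 30.
#' @param seed Integer seed; the series is a pure function of the arguments.
#' @param diurnal_amplitude Amplitude of the diurnal sinusoid (deg C).
#' @param monthly_anomaly_sd SD of the per-calendar-month anomaly (deg C).
#' @param start First timestamp (UTC midnight of a January 1st by default).
#' @param site_code Site label to attach.
#' @return A [temperature_series()].
#' @export
simulate_station_series <- function(seasonal, trend_slope = 0, noise_sd = 0.5,
                                    n_years = 3, resolution_minutes = 30,
                                    seed = 1, diurnal_amplitude = 3,
                                    monthly_anomaly_sd = 0,
                                    start = as.POSIXct("2006-01-01 00:00:00",
                                                       tz = "UTC"),
                                    site_code = "SYN") {
  stopifnot(length(seasonal) == 12L, n_years >= 1)
  if (!resolution_minutes %in% c(1L, 30L)) {
    stop("`resolution_minutes` must be 1 or 30", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)

  start_year <- as.integer(format(start, "%Y"))
  end <- as.POSIXct(sprintf("%d-01-01 00:00:00", start_year + n_years),
                    tz = "UTC")
  times <- seq(start, end - resolution_minutes * 60,
               by = resolution_minutes * 60)
  lt <- as.POSIXlt(times)
  month <- lt$mon + 1L
  year <- lt$year + 1900L
  hod <- lt$hour + lt$min / 60
  years_elapsed <- as.numeric(difftime(times, start, units = "days")) / 365.25
  diurnal <- diurnal_amplitude * sin(2 * pi * (hod - 9) / 24)

  set.seed(seed)
  ym <- year * 100L + month
  uym <- sort(unique(ym))
  anomaly <- setNames(rnorm(length(uym), 0, monthly_anomaly_sd),
                      as.character(uym))
  value <- seasonal[month] + trend_slope * years_elapsed + diurnal +
    anomaly[as.character(ym)] + rnorm(length(times), 0, noise_sd)

  temperature_series(tibble(timestamp = times, temp_c = unname(value)),
                     site_code = site_code,
                     resolution_minutes = resolution_minutes)
}

#' Simulate paired air / in-canopy temperature readings
#'
#' Emulates the 15-day paired logger campaign: air temperatures drawn
#' uniformly over a stated range and canopy temperatures generated from a
#' linear canopy model plus Gaussian residuals.
#'
#' @param model A one-row canopy model (see [canopy_models()]) or any list
#'   with `intercept` and `slope`.
#' @param n Number of pairs (>= 2).
#' @param resid_sd Residual SD around the fitted line (deg C).
#' @param seed Integer seed.
#' @param tair_range Range of air temperatures sampled (deg C).
#' @return Tibble with columns `tair`, `tplt`.
#' @export
simulate_canopy_pairs <- function(model, n, resid_sd = 0, seed = 1,
                                  tair_range = c(5, 25)) {
  stopifnot(n >= 2)
  set.seed(seed)
  tair <- runif(n, tair_range[1], tair_range[2])
  tplt <- model$intercept + model$slope * tair + rnorm(n, 0, resid_sd)
  tibble(tair = tair, tplt = tplt)
}

#' Simulate the field mosaic of a site
#'
#' Draws exactly `site$n_fields` field records: crop from the site's crop
#' mix, initial phenological stage from `stage_props` (bare soil has stage
#' `"none"`), log-normal field areas matched to the site's mean/SD field
#' size, and the elevation band from the site elevation.
#'
#' @param site A [site_spec()] or packaged site code.
#' @param seed Integer seed.
#' @param stage_props Proportions of observed phenological stages 1 and 2
#'   used for the random initial stage.
#' @return Tibble of field records: `field_id`, `area`, `crop`, `stage`,
#'   `elevation_band`, `months_in_stage`.
#' @export
simulate_landscape <- function(site, seed = 1,
                               stage_props = c("1" = 0.5, "2" = 0.5)) {
  site <- get_site_spec(site)
  set.seed(seed)
  n <- site$n_fields
  crop <- sample(names(site$crop_mix), n, replace = TRUE,
                 prob = site$crop_mix)
  stage <- ifelse(crop == "bare_soil", "none",
                  sample(names(stage_props), n, replace = TRUE,
                         prob = stage_props))
  cv2 <- (site$sd_field_area / site$mean_field_area)^2
  sdlog <- sqrt(log(1 + cv2))
  meanlog <- log(site$mean_field_area) - sdlog^2 / 2
  area <- rlnorm(n, meanlog, sdlog)
  tibble(
    field_id = sprintf("%s-F%03d", gsub("\\s+", "", site$site_code), seq_len(n)),
    area = area, crop = crop, stage = stage,
    elevation_band = elevation_band(site$elevation),
    months_in_stage = 0L
  )
}

#' Simulate monthly trap-count abundances from a known linear model
#'
#' Generates replicate monthly counts per site x month as
#' `max(0, round(linear predictor + N(0, noise_sd)))`, where the linear
#' predictor is a known combination of performance-summary terms. This is
#' the ground-truth generator mirrored by the stepwise regression: every
#' name in `true_coefs` (other than `intercept`) must be a candidate term
#' of the design matrix built from `summaries` (e.g. `S`, `temp`, `q3F`).
#'
#' @param summaries Performance summaries per site x month, from
#'   [summarize_performance()] (possibly row-bound over sites).
#' @param true_coefs Named numeric vector/list of true coefficients; use
#'   `intercept` for the constant.
#' @param noise_sd Count-scale Gaussian noise SD.
#' @param n_replicates Replicate counts per site x month (the study pooled
#'   6 monitoring years into 6 replicates per month).
#' @param seed Integer seed.
#' @return Tibble `site`, `month`, `replicate`, `count`.
#' @export
simulate_abundances <- function(summaries, true_coefs, noise_sd = 5,
                                n_replicates = 6, seed = 1) {
  true_coefs <- unlist(true_coefs)
  preds <- candidate_predictors(summaries)
  term_names <- setdiff(names(true_coefs), c("intercept", "(Intercept)"))
  unknown <- setdiff(term_names, names(preds))
  if (length(unknown) > 0) {
    stop("unknown term(s) in `true_coefs`: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  icpt <- sum(true_coefs[names(true_coefs) %in% c("intercept", "(Intercept)")])
  lp <- rep(icpt, nrow(preds))
  for (tm in term_names) lp <- lp + true_coefs[[tm]] * preds[[tm]]

  set.seed(seed)
  out <- tidyr::crossing(
    dplyr::select(dplyr::mutate(preds, .lp = lp), "site", "month", ".lp"),
    replicate = seq_len(n_replicates)
  )
  out$count <- pmax(0, round(out$.lp + rnorm(nrow(out), 0, noise_sd)))
  dplyr::select(out, "site", "month", "replicate", "count")
}
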