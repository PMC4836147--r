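# shared fixture builders; everything is generated in code at test time

# a canopy model row from the packaged table
canopy_row <- function(band, crop, stage, models = canopy_models()) {
  row <- models[models$band == band & models$crop == crop &
                  models$stage == as.character(stage), ]
  stopifnot(nrow(row) == 1L)
  row
}

# tiny site spec for fast landscape tests
toy_site <- function(n_fields = 10, crop_mix = default_crop_mix(),
                     mean_temp = 12, sd_temp = 0.5, elevation = 2700) {
  site_spec("Toy", elevation = elevation, n_fields = n_fields,
            mean_annual_temp = mean_temp, intra_annual_sd = sd_temp,
            crop_mix = crop_mix)
}

# monthly mean series built directly (year, month, temp_c), consecutive
toy_monthly <- function(values, start_year = 2006, start_month = 1) {
  n <- length(values)
  idx <- (start_year * 12 + start_month - 1) + seq_len(n) - 1
  tibble::tibble(year = idx %/% 12, month = idx %% 12 + 1, temp_c = values)
}

# a degenerate ensemble with the same value v every month
flat_ensemble <- function(v, n_per_month = 5, provenance = "station") {
  monthly_ensemble(
    tidyr::expand_grid(month = 1:12, year = seq_len(n_per_month)) |>
      dplyr::mutate(value = v),
    site_code = "Toy", provenance = provenance)
}

# single-species parameter bundle with mild inactivation, optimum ~17 C
toy_species <- function() {
  list(survival = schoolfield_params(d = 0.95, e = 8000, f = -120000,
                                     g = 283, h = 140000, i = 293),
       development = schoolfield_params(d = 0.10, e = 15000, f = -90000,
                                        g = 281.5, h = 110000, i = 292),
       fecundity = fecundity_params(o = 5, p = 120, q = 16, r = 4, s = 3))
}

# performance summaries for the four packaged sites over a chosen dataset,
# with a fixed random-component model so no decomposition is needed
toy_summaries <- function(provenance = c("microclimate", "station",
                                         "worldclim"),
                          n_years = 8, sigma = 0.5, seed = 1) {
  provenance <- match.arg(provenance)
  rcm <- list(mu = 0, sigma = sigma)
  out <- lapply(names(site_specs()), function(code) {
    spec <- get_site_spec(code)
    wc <- make_worldclim_fixture(spec)
    if (provenance == "worldclim") return(summarize_performance(wc, toy_species()))
    st <- simulate_station_ensemble(wc, rcm, n_years, seed = seed)
    if (provenance == "station") return(summarize_performance(st, toy_species()))
    land <- simulate_landscape(spec, seed = seed)
    mc <- build_microclimate_ensemble(st, land)
    summarize_performance(mc, toy_species())
  })
  res <- dplyr::bind_rows(out)
  attr(res, "provenance") <- provenance
  res
}
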