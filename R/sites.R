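#' Site specification
#'
#' A `site_spec` describes one monitored landscape: its elevation, number of
#' crop fields within the 250 m monitoring radius, the 50-year monthly
#' climatology statistics (annual mean and intra-annual standard deviation of
#' monthly temperature), and the crop composition of the field mosaic.
#'
#' @param site_code Short site label, e.g. `"Highland 1"`.
#' @param elevation Elevation in metres above sea level.
#' @param n_fields Number of fields in the landscape (> 0).
#' @param mean_annual_temp Annual mean of the monthly climatology (deg C).
#' @param intra_annual_sd Standard deviation of the 12 monthly climatology
#'   values (deg C, >= 0).
#' @param crop_mix Named numeric vector of crop proportions summing to 1.
#'   Names must be among `"alfalfa"`, `"bean"`, `"corn"`, `"pasture"`,
#'   `"potato"`, `"bare_soil"`. Default: uniform over the five crops plus
#'   10% bare soil.
#' @param mean_field_area,sd_field_area Field-area distribution (m^2) used
#'   when simulating landscapes.
#' @param local_name Optional local site name.
#' @param mean_monthly_abundance Optional typical monthly trap count, used
#'   only to scale synthetic abundances.
#'
#' @return An object of class `site_spec`.
#' @export
site_spec <- function(site_code, elevation, n_fields, mean_annual_temp,
                      intra_annual_sd, crop_mix = default_crop_mix(),
                      mean_field_area = 3000, sd_field_area = 1500,
                      local_name = NA_character_,
                      mean_monthly_abundance = NA_real_) {
  stopifnot(is.character(site_code), length(site_code) == 1L)
  if (!is.numeric(n_fields) || n_fields < 1) {
    stop("`n_fields` must be a positive count", call. = FALSE)
  }
  if (intra_annual_sd < 0) {
    stop("`intra_annual_sd` must be >= 0", call. = FALSE)
  }
  if (is.null(names(crop_mix)) || !all(names(crop_mix) %in% PESTCLIM_CROPS)) {
    stop("`crop_mix` must be named with known crops: ",
         paste(PESTCLIM_CROPS, collapse = ", "), call. = FALSE)
  }
  if (abs(sum(crop_mix) - 1) > 1e-9) {
    stop("`crop_mix` proportions must sum to 1", call. = FALSE)
  }
  structure(
    list(site_code = site_code, elevation = elevation,
         n_fields = as.integer(n_fields),
         mean_annual_temp = mean_annual_temp,
         intra_annual_sd = intra_annual_sd, crop_mix = crop_mix,
         mean_field_area = mean_field_area, sd_field_area = sd_field_area,
         local_name = local_name,
         mean_monthly_abundance = mean_monthly_abundance),
    class = "site_spec"
  )
}

#' @export
print.site_spec <- function(x, ...) {
  cat(sprintf("<site_spec> %s (%s), %d m a.s.l., %d fields, %.2f +/- %.2f degC\n",
              x$site_code, x$local_name, round(x$elevation), x$n_fields,
              x$mean_annual_temp, x$intra_annual_sd))
  invisible(x)
}

#' Default crop mix: uniform over the five crops plus 10% bare soil
#' @return Named numeric vector of proportions.
#' @export
default_crop_mix <- function() {
  c(alfalfa = 0.18, bean = 0.18, corn = 0.18, pasture = 0.18,
    potato = 0.18, bare_soil = 0.10)
}

#' Packaged site specifications for the four monitored sites
#'
#' Reads the packaged site table (two lowland sites at ~2700 m and two
#' highland sites at ~3200 m in the central Ecuadorian Andes) into a named
#' list of [site_spec()] objects.
#'
#' @param path Path to a YAML site table; defaults to the packaged one.
#' @return Named list of `site_spec` objects.
#' @export
site_specs <- function(path = system.file("extdata", "sites.yaml",
                                          package = "pestclim")) {
  raw <- yaml::read_yaml(path)
  specs <- lapply(names(raw), function(code) {
    s <- raw[[code]]
    site_spec(site_code = code, elevation = s$elevation,
              n_fields = s$n_fields, mean_annual_temp = s$mean_annual_temp,
              intra_annual_sd = s$intra_annual_sd,
              mean_field_area = s$mean_field_area %||% 3000,
              sd_field_area = s$sd_field_area %||% 1500,
              local_name = s$local_name %||% NA_character_,
              mean_monthly_abundance = s$mean_monthly_abundance %||% NA_real_)
  })
  names(specs) <- names(raw)
  specs
}

#' Look up a packaged site by code
#' @param site_code Site code, e.g. `"Lowland 2"`.
#' @param specs List of specs to search (default: packaged sites).
#' @return A `site_spec`.
#' @export
get_site_spec <- function(site_code, specs = site_specs()) {
  if (inherits(site_code, "site_spec")) return(site_code)
  if (!site_code %in% names(specs)) {
    stop("unknown site code: '", site_code, "'", call. = FALSE)
  }
  specs[[site_code]]
}

#' Elevation band for the canopy-model table
#'
#' Sites below 3000 m fall in the low band `"A"`, others in the high band
#' `"B"` (the monitored sites group as 2713/2727 m vs 3152/3280 m).
#'
#' @param elevation Elevation in metres.
#' @return `"A"` or `"B"`.
#' @export
elevation_band <- function(elevation) {
  ifelse(elevation < 3000, "A", "B")
}
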