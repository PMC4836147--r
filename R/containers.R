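#' Monthly temperature ensemble
#'
#' The common currency of the pipeline: for each calendar month 1-12, a set
#' of temperature values (deg C) carrying temporal (across-years) and/or
#' spatial (across-fields) variance. A climatology-derived ensemble
#' (`provenance = "worldclim"`) has exactly one value per month; a
#' station-derived ensemble has one value per simulated year; a
#' microclimate-derived ensemble has one value per year x field.
#'
#' @param data Tibble/data frame with at least columns `month` (integer
#'   1-12) and `value` (finite deg C); extra columns (e.g. `year`,
#'   `field_id`) are kept.
#' @param site_code Site label.
#' @param provenance One of `"worldclim"`, `"station"`, `"microclimate"`.
#' @return A tibble of class `monthly_ensemble` with attributes
#'   `site_code` and `provenance`.
#' @export
monthly_ensemble <- function(data, site_code, provenance) {
  provenance <- match.arg(provenance, c("worldclim", "station", "microclimate"))
  data <- as_tibble(data)
  stopifnot(all(c("month", "value") %in% names(data)))
  if (!all(data$month %in% 1:12)) {
    stop("ensemble months must be in 1..12", call. = FALSE)
  }
  if (!all(is.finite(data$value))) {
    stop("ensemble values must be finite", call. = FALSE)
  }
  counts <- table(factor(data$month, levels = 1:12))
  if (any(counts == 0)) {
    stop("every month 1..12 needs at least one value", call. = FALSE)
  }
  if (provenance == "worldclim" && any(counts != 1)) {
    stop("a worldclim ensemble has exactly one value per month", call. = FALSE)
  }
  structure(data, class = c("monthly_ensemble", class(data)),
            site_code = site_code, provenance = provenance)
}

#' @export
print.monthly_ensemble <- function(x, ...) {
  cat(sprintf("<monthly_ensemble> site %s, provenance %s, %d values (%d-%d per month)\n",
              attr(x, "site_code"), attr(x, "provenance"), nrow(x),
              min(table(x$month)), max(table(x$month))))
  NextMethod()
}

#' Monthly values of an ensemble as a 12-vector (one value per month)
#'
#' For a climatology ensemble this is the 12 packaged values; otherwise the
#' per-month means.
#'
#' @param ensemble A [monthly_ensemble()].
#' @return Numeric vector of length 12 (January..December).
#' @export
ensemble_monthly_values <- function(ensemble) {
  out <- tapply(ensemble$value, factor(ensemble$month, levels = 1:12), mean)
  as.numeric(out)
}

#' Timestamped temperature series
#'
#' @param data Tibble with columns `timestamp` (POSIXct, strictly
#'   increasing) and `temp_c` (finite).
#' @param site_code Site label.
#' @param resolution_minutes Logger resolution (1 or 30 minutes).
#' @return A tibble of class `temperature_series`.
#' @export
temperature_series <- function(data, site_code, resolution_minutes) {
  data <- as_tibble(data)
  stopifnot(all(c("timestamp", "temp_c") %in% names(data)))
  if (nrow(data) == 0L) stop("empty temperature series", call. = FALSE)
  if (any(diff(as.numeric(data$timestamp)) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  if (!all(is.finite(data$temp_c))) {
    stop("temperatures must be finite", call. = FALSE)
  }
  structure(data, class = c("temperature_series", class(data)),
            site_code = site_code,
            resolution_minutes = as.integer(resolution_minutes))
}

#' Write / read a temperature series as CSV (ISO-8601 timestamp, temperature_c)
#' @param series A [temperature_series()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_temperature_series <- function(series, path) {
  df <- data.frame(
    timestamp = format(series$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    temperature_c = series$temp_c
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_temperature_series
#' @param site_code,resolution_minutes Metadata to attach on read.
#' @export
read_temperature_series <- function(path, site_code = NA_character_,
                                    resolution_minutes = 30L) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  temperature_series(
    tibble(timestamp = as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                                  tz = "UTC"),
           temp_c = df$temperature_c),
    site_code = site_code, resolution_minutes = resolution_minutes
  )
}
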