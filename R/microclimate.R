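#' Packaged air-to-canopy temperature models
#'
#' Reads the table of linear models relating air temperature (`Tair`, 1.5 m
#' logger height) to air temperature inside the crop canopy (`Tplt`), one
#' row per elevation band x crop x phenological stage (20 rows: five crops,
#' two stages, two bands). Bare soil carries no model: air temperature is
#' taken as-is (differences in the first 2 m above bare ground are
#' negligible). Significance is stored as a categorical flag.
#'
#' @param path CSV path; defaults to the packaged table.
#' @return Tibble `band`, `crop`, `stage`, `intercept`, `slope`,
#'   `r_squared`, `p_flag`.
#' @export
canopy_models <- function(path = system.file("extdata", "canopy_models.csv",
                                             package = "pestclim")) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(stage = "character"))
  as_tibble(df)
}

#' Fit a linear canopy model from paired readings
#'
#' Ordinary least squares of in-canopy on air temperature for one band x
#' crop x stage combination.
#'
#' @param pairs Tibble with columns `tair`, `tplt` (>= 3 rows; `tair` must
#'   vary).
#' @param band,crop,stage Labels stored with the fit.
#' @return One-row tibble with `band`, `crop`, `stage`, `intercept`,
#'   `slope`, `r_squared`, `p_value` (slope p-value).
#' @export
fit_canopy_model <- function(pairs, band = "A", crop = "potato", stage = "1") {
  if (nrow(pairs) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (sd(pairs$tair) == 0) {
    stop("degenerate `tair`: no variance to fit a slope", call. = FALSE)
  }
  fit <- lm(tplt ~ tair, data = pairs)
  sm <- summary(fit)
  tibble(band = band, crop = crop, stage = as.character(stage),
         intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
         r_squared = sm$r.squared,
         p_value = unname(sm$coefficients["tair", "Pr(>|t|)"]))
}

#' Apply a canopy model to air temperatures
#'
#' `intercept + slope * tair` for crop models; the identity for bare soil
#' (`model` of crop `"bare_soil"` or `NULL`).
#'
#' @param model One-row canopy model, or `NULL`/bare-soil for the identity.
#' @param tair Air temperatures (deg C), vectorised.
#' @return In-canopy temperatures (deg C).
#' @export
apply_canopy_model <- function(model, tair) {
  if (is.null(model) ||
      (!is.null(model$crop) && model$crop[1] == "bare_soil")) {
    return(tair)
  }
  model$intercept[1] + model$slope[1] * tair
}

#' Crop rotation schedule
#'
#' A cyclic ordered track of `(crop, stage, duration in months)` entries.
#' Fields advance along the track month by month; bare-soil fields not
#' listed in the track persist unchanged.
#'
#' @param x A data frame with columns `crop`, `stage`, `duration`, or a
#'   path to a YAML file with a `track:` list of such entries.
#' @return Tibble of class `rotation_schedule`.
#' @export
rotation_schedule <- function(x) {
  if (is.character(x)) {
    raw <- yaml::read_yaml(x)$track
    x <- dplyr::bind_rows(lapply(raw, as_tibble))
  }
  x <- as_tibble(x)
  stopifnot(all(c("crop", "stage", "duration") %in% names(x)))
  if (nrow(x) < 1L) stop("schedule needs at least one entry", call. = FALSE)
  if (any(x$duration < 1)) stop("durations must be >= 1 month", call. = FALSE)
  x$stage <- as.character(x$stage)
  x$duration <- as.integer(x$duration)
  structure(x, class = c("rotation_schedule", class(x)))
}

#' @rdname rotation_schedule
#' @export
default_rotation <- function() {
  rotation_schedule(system.file("extdata", "rotation.yaml",
                                package = "pestclim"))
}

#' Advance a landscape along its rotation schedule
#'
#' Each field moves `months` months forward along the cyclic track from its
#' current position (entry start plus `months_in_stage`). Bare-soil fields
#' follow the schedule if listed, otherwise persist.
#'
#' @param fields Field records from [simulate_landscape()].
#' @param schedule A [rotation_schedule()].
#' @param months Whole months to advance (>= 0).
#' @return Field records with updated `crop`, `stage`, `months_in_stage`.
#' @export
advance_landscape <- function(fields, schedule, months) {
  stopifnot(months >= 0)
  key <- paste(fields$crop, fields$stage)
  skey <- paste(schedule$crop, schedule$stage)
  idx <- match(key, skey)
  movable <- !(fields$crop == "bare_soil" & is.na(idx))
  if (any(is.na(idx) & movable)) {
    bad <- unique(key[is.na(idx) & movable])
    stop("field state(s) not in rotation schedule: ",
         paste(bad, collapse = "; "), call. = FALSE)
  }
  if (!any(movable) || months == 0) return(fields)

  starts <- c(0L, cumsum(schedule$duration))
  total <- starts[length(starts)]
  mis <- fields$months_in_stage %||% rep(0L, nrow(fields))
  pos <- (starts[idx[movable]] + mis[movable] + months) %% total
  entry <- findInterval(pos, starts, rightmost.closed = FALSE)
  fields$crop[movable] <- schedule$crop[entry]
  fields$stage[movable] <- schedule$stage[entry]
  fields$months_in_stage[movable] <- as.integer(pos - starts[entry])
  fields
}

# resolve (band, crop, stage) -> (intercept, slope), identity for bare soil
canopy_coefs_for <- function(fields, models) {
  icpt <- numeric(nrow(fields))
  slope <- rep(1, nrow(fields))
  cropped <- fields$crop != "bare_soil"
  if (any(cropped)) {
    mk <- paste(models$band, models$crop, models$stage)
    fk <- paste(fields$elevation_band, fields$crop, fields$stage)[cropped]
    j <- match(fk, mk)
    if (any(is.na(j))) {
      stop("no canopy model for field state(s): ",
           paste(unique(fk[is.na(j)]), collapse = "; "), call. = FALSE)
    }
    icpt[cropped] <- models$intercept[j]
    slope[cropped] <- models$slope[j]
  }
  list(intercept = icpt, slope = slope)
}

#' Build the landscape-level microclimate ensemble
#'
#' For each calendar month, the rotation is advanced to that month and every
#' station ensemble value (one per simulated year) is pushed through the
#' canopy model of every field's current crop x stage x band; bare soil
#' passes air temperature through unchanged. The air-to-canopy relationship
#' is held constant over the year. The resulting ensemble carries both the
#' between-year variance of the station ensemble and the across-field
#' spatial variance: each month holds `n_years * n_fields` values.
#'
#' @param station A station-provenance [monthly_ensemble()].
#' @param fields Field records (see [simulate_landscape()]).
#' @param models Canopy model table (default: packaged).
#' @param schedule A [rotation_schedule()] (default: packaged).
#' @param seed Unused; the transform is deterministic (fitted lines only, no
#'   residual noise re-added). Accepted for calling-convention symmetry.
#' @return A [monthly_ensemble()] with provenance `"microclimate"` and
#'   columns `month`, `year`, `field_id`, `value`.
#' @export
build_microclimate_ensemble <- function(station, fields,
                                        models = canopy_models(),
                                        schedule = default_rotation(),
                                        seed = NULL) {
  if (nrow(station) == 0L) stop("empty station ensemble", call. = FALSE)
  per_month <- lapply(1:12, function(m) {
    st <- station[station$month == m, ]
    flds <- advance_landscape(fields, schedule, m - 1L)
    cf <- canopy_coefs_for(flds, models)
    # |years| x |fields| grid of canopy temperatures
    vals <- outer(st$value, cf$slope) +
      matrix(cf$intercept, nrow = nrow(st), ncol = nrow(fields), byrow = TRUE)
    tibble(month = m,
           year = rep(st$year %||% seq_len(nrow(st)), times = nrow(fields)),
           field_id = rep(flds$field_id, each = nrow(st)),
           value = as.vector(vals))
  })
  monthly_ensemble(dplyr::bind_rows(per_month),
                   site_code = attr(station, "site_code"),
                   provenance = "microclimate")
}
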