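#' Aggregate a temperature series to monthly means
#'
#' @param series A [temperature_series()].
#' @return Tibble `year`, `month`, `temp_c` (one arithmetic mean per calendar
#'   month present in the series), ordered in time. Months with no readings
#'   are simply absent.
#' @export
aggregate_to_monthly <- function(series) {
  if (is.null(series) || nrow(series) == 0L) {
    stop("cannot aggregate an empty series", call. = FALSE)
  }
  lt <- as.POSIXlt(series$timestamp)
  out <- tibble(year = lt$year + 1900L, month = lt$mon + 1L,
                temp_c = series$temp_c) |>
    dplyr::group_by(.data$year, .data$month) |>
    dplyr::summarise(temp_c = mean(.data$temp_c), .groups = "drop") |>
    dplyr::arrange(.data$year, .data$month)
  attr(out, "site_code") <- attr(series, "site_code")
  out
}

#' Classical additive decomposition of a monthly series
#'
#' Splits a monthly mean series into trend (centred 12-term moving average
#' with half-weight endpoints), seasonal (month-wise means of the detrended
#' values, centred to sum to zero) and random components, the conventional
#' additive algorithm of standard statistics environments. The trend (and
#' hence the random component) is undefined in the first and last six
#' months.
#'
#' @param monthly Tibble `year`, `month`, `temp_c` from
#'   [aggregate_to_monthly()]; must cover at least 24 consecutive months.
#' @return Object of class `monthly_decomposition`: list with `monthly`,
#'   `trend`, `seasonal` (12 values, January..December, summing to zero) and
#'   `random`.
#' @export
decompose_monthly <- function(monthly) {
  if (nrow(monthly) < 24L) {
    stop("decomposition needs at least 24 months of data", call. = FALSE)
  }
  idx <- monthly$year * 12L + monthly$month
  if (any(diff(idx) != 1L)) {
    stop("monthly series must be consecutive (no missing months)",
         call. = FALSE)
  }
  x <- ts(monthly$temp_c, start = c(monthly$year[1], monthly$month[1]),
          frequency = 12)
  dec <- stats::decompose(x, type = "additive")
  seasonal <- numeric(12)
  seasonal[((monthly$month[1] - 1L + 0:11) %% 12L) + 1L] <-
    as.numeric(dec$figure)
  structure(
    list(monthly = monthly, trend = as.numeric(dec$trend),
         seasonal = seasonal, random = as.numeric(dec$random)),
    class = "monthly_decomposition"
  )
}

#' @export
print.monthly_decomposition <- function(x, ...) {
  cat(sprintf("<monthly_decomposition> %d months, seasonal range %.2f degC\n",
              nrow(x$monthly), diff(range(x$seasonal))))
  invisible(x)
}

#' Pearson cross-correlation at lag 0 between two seasonal profiles
#'
#' Used to check that the seasonal component of a station series agrees with
#' the reference climatology seasonality before that climatology is adopted
#' as the seasonal backbone of simulated ensembles.
#'
#' @param a,b Numeric vectors of 12 seasonal values with nonzero variance.
#' @return Correlation in `[-1, 1]`.
#' @export
cross_correlation_lag0 <- function(a, b) {
  if (length(a) != 12L || length(b) != 12L) {
    stop("seasonal profiles must have 12 values", call. = FALSE)
  }
  if (sd(a) == 0 || sd(b) == 0) {
    stop("seasonal profiles must have nonzero variance", call. = FALSE)
  }
  stats::cor(a, b)
}

#' Fit a Gaussian model to the random component of a monthly series
#'
#' Decomposes the series, drops the edge months where the trend (and hence
#' the random component) is undefined, and fits a Gaussian by maximum
#' likelihood. Shapiro-Wilk normality statistics are reported, never
#' enforced: a rejection triggers a warning and the fit proceeds.
#'
#' @param monthly Tibble from [aggregate_to_monthly()] (>= 24 consecutive
#'   months).
#' @return Object of class `random_component_model`: list with `mu`,
#'   `sigma` (ML estimate, divisor n), `shapiro_w`, `shapiro_p`, `n`.
#' @export
detrend_and_fit_random <- function(monthly) {
  dec <- decompose_monthly(monthly)
  r <- dec$random[!is.na(dec$random)]
  if (length(r) < 3L) {
    stop("need at least 3 non-missing random values", call. = FALSE)
  }
  mu <- mean(r)
  sigma <- sqrt(mean((r - mu)^2))
  if (diff(range(r)) < 1e-10) {
    # (numerically) constant random component: normality is vacuous
    sw <- list(statistic = c(W = 1), p.value = 1)
  } else {
    sw <- shapiro.test(r)
  }
  if (sw$p.value < 0.05) {
    warning("random component departs from Gaussian (Shapiro-Wilk p = ",
            signif(sw$p.value, 3), "); Gaussian fit proceeds", call. = FALSE)
  }
  structure(list(mu = mu, sigma = sigma,
                 shapiro_w = unname(sw$statistic),
                 shapiro_p = sw$p.value, n = length(r)),
            class = "random_component_model")
}

#' @export
print.random_component_model <- function(x, ...) {
  cat(sprintf(
    "<random_component_model> N(%.3f, %.3f) on %d months; Shapiro-Wilk W = %.3f, p = %.3f\n",
    x$mu, x$sigma, x$n, x$shapiro_w, x$shapiro_p))
  invisible(x)
}

#' Simulate a station monthly ensemble around a reference seasonality
#'
#' For each month m and simulated year y, draws
#' `reference_seasonal[m] + N(mu, sigma)`, producing an ensemble that
#' carries the between-year monthly variance estimated from the station
#' record while adopting the reference climatology as seasonal backbone.
#'
#' @param reference_seasonal A worldclim-provenance [monthly_ensemble()] or
#'   a plain 12-vector of monthly reference temperatures (deg C).
#' @param model A [detrend_and_fit_random()] result (or list with `mu`,
#'   `sigma`).
#' @param n_years Number of simulated years (>= 1).
#' @param seed Integer seed.
#' @param site_code Site label; defaults to the reference's, if any.
#' @return A [monthly_ensemble()] with provenance `"station"` and columns
#'   `month`, `year`, `value` (`n_years` values per month).
#' @export
simulate_station_ensemble <- function(reference_seasonal, model, n_years,
                                      seed = 1, site_code = NULL) {
  if (inherits(reference_seasonal, "monthly_ensemble")) {
    site_code <- site_code %||% attr(reference_seasonal, "site_code")
    reference_seasonal <- ensemble_monthly_values(reference_seasonal)
  }
  stopifnot(length(reference_seasonal) == 12L, n_years >= 1)
  if (model$sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  set.seed(seed)
  grid <- tidyr::expand_grid(month = 1:12, year = seq_len(n_years))
  grid$value <- reference_seasonal[grid$month] +
    rnorm(nrow(grid), model$mu, model$sigma)
  monthly_ensemble(grid, site_code = site_code %||% "SYN",
                   provenance = "station")
}
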