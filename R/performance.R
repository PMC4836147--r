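#' Sharpe-Schoolfield thermal performance parameters
#'
#' Parameters of the thermodynamic enzyme-kinetics rate model used for both
#' development and survival rates: `d` is the rate at the 298.16 K reference
#' temperature (in the absence of inactivation), `e` the activation
#' energy-like term, `f`/`g` and `h`/`i` the low- and high-temperature
#' inactivation energies and temperatures (energies in cal/mol with gas
#' constant R = 1.987; `g`, `i` in Kelvin).
#'
#' @param d,e,f,g,h,i Model parameters; `d >= 0`, `g > 0`, `i > 0`.
#' @return List of class `schoolfield_params`.
#' @export
schoolfield_params <- function(d, e, f, g, h, i) {
  if (d < 0) stop("`d` must be >= 0", call. = FALSE)
  if (g <= 0 || i <= 0) stop("`g` and `i` are Kelvin and must be > 0",
                             call. = FALSE)
  structure(list(d = d, e = e, f = f, g = g, h = h, i = i),
            class = "schoolfield_params")
}

#' Gamma-type fecundity parameters
#'
#' @param o Baseline eggs per female (value far from the optimum).
#' @param p Peak increment: fecundity at the peak temperature is `o + p`.
#' @param q Peak temperature (deg C).
#' @param r Width scale (deg C, nonzero).
#' @param s Shape (> 1).
#' @return List of class `fecundity_params`.
#' @export
fecundity_params <- function(o, p, q, r, s) {
  if (r == 0) stop("`r` must be nonzero", call. = FALSE)
  if (s <= 1) stop("`s` must be > 1", call. = FALSE)
  structure(list(o = o, p = p, q = q, r = r, s = s),
            class = "fecundity_params")
}

# gas constant on the cal/(mol K) scale used by the rate model
SCHOOLFIELD_R <- 1.987
# the model's reference temperature, kept verbatim (not "corrected" to 298.15)
SCHOOLFIELD_TREF <- 298.16

#' Sharpe-Schoolfield rate at a given Kelvin temperature
#'
#' `rate(T) = d * (T/298.16) * exp[(e/R) (1/298.16 - 1/T)] /
#' (1 + exp[(f/R) (1/g - 1/T)] + exp[(h/R) (1/i - 1/T)])`, with R = 1.987.
#' The two denominator exponentials encode low- and high-temperature enzyme
#' inactivation. Exponent arguments are capped to avoid floating-point
#' overflow; the rate is then finite and non-negative for all finite T > 0.
#'
#' @param params A [schoolfield_params()].
#' @param temp_k Temperature(s) in Kelvin (> 0).
#' @return Rate(s) on the scale of `d`.
#' @export
schoolfield_rate <- function(params, temp_k) {
  if (any(temp_k <= 0)) stop("Kelvin temperature must be > 0", call. = FALSE)
  R <- SCHOOLFIELD_R
  cap <- function(x) pmin(x, 700)
  num <- params$d * (temp_k / SCHOOLFIELD_TREF) *
    exp(cap((params$e / R) * (1 / SCHOOLFIELD_TREF - 1 / temp_k)))
  den <- 1 + exp(cap((params$f / R) * (1 / params$g - 1 / temp_k))) +
    exp(cap((params$h / R) * (1 / params$i - 1 / temp_k)))
  num / den
}

#' Gamma-type fecundity at a given Celsius temperature
#'
#' `F(T) = o + p * exp(-x) * ((x + s - 1)/(s - 1))^(s-1)` with
#' `x = (T - q)/r`, defined where `x + s - 1 > 0` and clamped to the
#' baseline `o` outside. The curve peaks at `o + p` at `T = q` and decays
#' to `o` far above the optimum.
#'
#' @param params A [fecundity_params()].
#' @param temp_c Temperature(s) in deg C, vectorised.
#' @return Eggs per female.
#' @export
gamma_fecundity <- function(params, temp_c) {
  if (params$s <= 1) stop("`s` must be > 1", call. = FALSE)
  x <- (temp_c - params$q) / params$r
  out <- rep(params$o, length(x))
  ok <- (x + params$s - 1) > 0
  out[ok] <- params$o + params$p * exp(-x[ok]) *
    ((x[ok] + params$s - 1) / (params$s - 1))^(params$s - 1)
  out
}

#' Packaged species parameter sets
#'
#' Loads the packaged placeholder thermal-performance parameters for the
#' three potato tuber moth species. Each species is a list with elements
#' `survival` and `development` ([schoolfield_params()]) and `fecundity`
#' ([fecundity_params()]).
#'
#' @param path YAML path; defaults to the packaged file.
#' @return Named list of species parameter bundles.
#' @export
species_params <- function(path = system.file("extdata", "species_params.yaml",
                                              package = "pestclim")) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(sp) {
    list(survival = do.call(schoolfield_params, sp$survival),
         development = do.call(schoolfield_params, sp$development),
         fecundity = do.call(fecundity_params, sp$fecundity))
  })
}

# evaluate the three curves at temp_c, averaged over species bundles;
# survival clamped to [0, 1] per species before averaging
evaluate_performance <- function(temp_c, species) {
  if (!is.null(species$survival)) species <- list(species)
  temp_k <- temp_c + 273.15
  acc <- list(S = 0, D = 0, F = 0)
  for (sp in species) {
    acc$S <- acc$S + pmin(pmax(schoolfield_rate(sp$survival, temp_k), 0), 1)
    acc$D <- acc$D + schoolfield_rate(sp$development, temp_k)
    acc$F <- acc$F + gamma_fecundity(sp$fecundity, temp_c)
  }
  lapply(acc, function(v) v / length(species))
}

#' Summarize pest performance over a monthly ensemble
#'
#' Applies the survival, development and fecundity curves to every value of
#' the ensemble (Celsius values are converted to Kelvin for the rate model;
#' survival is clamped to `[0, 1]`), averaging across species when several
#' parameter bundles are given, then reports the mean and quartiles of each
#' metric and of raw temperature per calendar month. For a climatology
#' ensemble (one value per month) all quartiles equal that single value.
#'
#' @param ensemble A [monthly_ensemble()].
#' @param species One species parameter bundle (list with `survival`,
#'   `development`, `fecundity`) or a list of bundles to average, e.g.
#'   [species_params()].
#' @return Tibble with columns `site`, `month` and, for each of `temp`,
#'   `S`, `D`, `F`: `_mean`, `_q1`, `_median`, `_q3`. Carries the
#'   ensemble's provenance as attribute `provenance`.
#' @export
summarize_performance <- function(ensemble, species) {
  perf <- evaluate_performance(ensemble$value, species)
  df <- tibble(month = ensemble$month, temp = ensemble$value,
               S = perf$S, D = perf$D, F = perf$F)
  qtl <- function(x, p) unname(quantile(x, p, names = FALSE))
  out <- df |>
    dplyr::group_by(.data$month) |>
    dplyr::summarise(dplyr::across(
      dplyr::all_of(c("temp", "S", "D", "F")),
      list(mean = mean,
           q1 = function(x) qtl(x, 0.25),
           median = function(x) qtl(x, 0.50),
           q3 = function(x) qtl(x, 0.75)),
      .names = "{.col}_{.fn}"), .groups = "drop")
  out <- dplyr::mutate(out, site = attr(ensemble, "site_code") %||% NA_character_,
                       .before = 1)
  attr(out, "provenance") <- attr(ensemble, "provenance")
  out
}

#' Relative difference between two aligned performance series
#'
#' `100 * (a - b) / b` per element; where `b == 0` the difference is
#' undefined and reported as `NA` rather than raising an error.
#'
#' @param a,b Aligned numeric vectors (e.g. per-month mean performances).
#' @return Percent differences, same length.
#' @export
relative_difference <- function(a, b) {
  if (length(a) != length(b)) stop("`a` and `b` must be aligned", call. = FALSE)
  out <- 100 * (a - b) / b
  out[b == 0] <- NA_real_
  out
}
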