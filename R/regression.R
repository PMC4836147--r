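# map candidate regression term names -> performance-summary columns;
# quartile terms are named q1X/q3X following the printed model formulas
CANDIDATE_MAP <- c(
  S = "S_mean", D = "D_mean", F = "F_mean", temp = "temp_mean",
  q1S = "S_q1", q1D = "D_q1", q1F = "F_q1", q1temp = "temp_q1",
  q3S = "S_q3", q3D = "D_q3", q3F = "F_q3", q3temp = "temp_q3"
)

# project summaries onto candidate-named predictor columns
candidate_predictors <- function(summaries) {
  prov <- attr(summaries, "provenance")
  map <- CANDIDATE_MAP
  if (identical(prov, "worldclim")) map <- map[c("S", "D", "F", "temp")]
  keep <- map[map %in% names(summaries)]
  out <- summaries[, c("site", "month", unname(keep))]
  names(out) <- c("site", "month", names(keep))
  attr(out, "candidates") <- names(keep)
  out
}

#' Build the regression design matrix
#'
#' Joins replicate abundance counts to the performance summary of their
#' site x month. The candidate predictors are the means of survival `S`,
#' development `D`, fecundity `F` and temperature `temp` plus their first
#' and third quartiles (`q1S` ... `q3temp`): 12 columns. For
#' climatology-derived summaries (a single value per month) the quartile
#' columns are excluded, leaving the 4 means. Replicates within a
#' site x month share the same predictor values.
#'
#' @param summaries Performance summaries from [summarize_performance()]
#'   (row-bind over sites, keeping the `provenance` attribute).
#' @param abundances Tibble `site`, `month`, `replicate`, `count`.
#' @return Tibble `site`, `month`, `replicate`, `count` plus candidate
#'   columns; attributes `candidates` and `provenance`.
#' @export
build_design_matrix <- function(summaries, abundances) {
  preds <- candidate_predictors(summaries)
  dm <- dplyr::left_join(as_tibble(abundances), preds,
                         by = c("site", "month"))
  cand <- attr(preds, "candidates")
  if (anyNA(dm[cand])) {
    bad <- unique(dm[!stats::complete.cases(dm[cand]), c("site", "month")])
    stop("abundance rows without a matching summary: ",
         paste(paste(bad$site, bad$month), collapse = "; "), call. = FALSE)
  }
  # degenerate ensembles (e.g. a single simulated year) make quartile
  # columns exact duplicates of the means; keep the first of each
  # duplicated set so the design stays full rank
  dup <- duplicated(lapply(dm[cand], function(x) round(x, 12)))
  if (any(dup)) {
    attr(dm, "dropped_duplicates") <- cand[dup]
    cand <- cand[!dup]
  }
  attr(dm, "candidates") <- cand
  attr(dm, "provenance") <- attr(summaries, "provenance")
  dm
}

#' Stepwise-AIC multiple linear regression of abundance
#'
#' Fits the full OLS model `count ~ <all candidates>` and runs a
#' bidirectional stepwise search (add/drop the single term giving the
#' largest AIC decrease, stopping at a local minimum). The reported AIC is
#' the full Gaussian-likelihood form `n log(2 pi RSS/n) + n + 2(k+1)`; the
#' search uses the same criterion up to an additive constant, so the
#' selected model is identical.
#'
#' @param dm Design matrix from [build_design_matrix()].
#' @return Object of class `abundance_model`: list with `selected_terms`,
#'   `coefficients`, `aic`, `r_squared`, `n_obs`, the underlying `fit` and
#'   the candidate set.
#' @export
stepwise_aic <- function(dm) {
  cand <- attr(dm, "candidates") %||%
    intersect(names(CANDIDATE_MAP), names(dm))
  if (nrow(dm) <= length(cand) + 2L) {
    stop("need n_obs > number of candidates + 2", call. = FALSE)
  }
  full <- reformulate(cand, response = "count")
  fit <- lm(full, data = dm)
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("singular design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sel <- step(fit, scope = list(lower = ~1, upper = full),
              direction = "both", trace = 0)
  structure(
    list(selected_terms = sort(attr(terms(sel), "term.labels")),
         coefficients = coef(sel), aic = AIC(sel),
         r_squared = summary(sel)$r.squared, n_obs = nrow(dm),
         candidates = cand, provenance = attr(dm, "provenance"),
         fit = sel),
    class = "abundance_model"
  )
}

#' @export
print.abundance_model <- function(x, ...) {
  rhs <- if (length(x$selected_terms)) paste(x$selected_terms, collapse = " + ")
         else "1"
  cat(sprintf("<abundance_model> count ~ %s\n  AIC %.1f, R-squared %.3f, n = %d\n",
              rhs, x$aic, x$r_squared, x$n_obs))
  invisible(x)
}

#' Predict abundances from a fitted model
#'
#' Evaluates the linear predictor on new performance summaries. Predictions
#' are on the model scale and deliberately not clipped at zero.
#'
#' @param model An [stepwise_aic()] result.
#' @param summaries Performance summaries covering all selected terms.
#' @return Tibble `site`, `month`, `predicted`.
#' @export
predict_abundance <- function(model, summaries) {
  preds <- candidate_predictors(summaries)
  missing <- setdiff(model$selected_terms, names(preds))
  if (length(missing) > 0) {
    stop("summaries lack selected term(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tibble(site = preds$site, month = preds$month,
         predicted = unname(predict(model$fit, newdata = preds)))
}

#' Temporal validation: observed vs predicted monthly abundances
#'
#' Two-sample (optionally paired) Student t-test of observed against
#' predicted values, plus the goodness-of-fit R-squared
#' `1 - RSS/TSS` and, when a model is supplied, its AIC.
#'
#' @param observed,predicted Aligned numeric vectors.
#' @param model Optional [stepwise_aic()] result whose AIC to report.
#' @param paired Use a paired t-test (default two-sample).
#' @return List with `t_p_value`, `aic`, `r_squared`.
#' @export
temporal_validation <- function(observed, predicted, model = NULL,
                                paired = FALSE) {
  stopifnot(length(observed) == length(predicted))
  p <- if (all(observed == predicted)) 1 else
    tryCatch(t.test(observed, predicted, paired = paired)$p.value,
             error = function(e) NA_real_)
  tss <- sum((observed - mean(observed))^2)
  rss <- sum((observed - predicted)^2)
  list(t_p_value = p,
       aic = if (is.null(model)) NA_real_ else model$aic,
       r_squared = 1 - rss / tss)
}

#' Spatial validation over an elevation gradient
#'
#' For each dataset's model, predicts abundances at a set of extra sites,
#' compares site-level mean predicted vs observed abundance as
#' `|predicted - observed| / observed * 100`, and regresses the per-site
#' absolute percent difference on elevation (a positive significant slope
#' means the model degrades with elevation).
#'
#' @param models Named list of [stepwise_aic()] results (one per dataset).
#' @param summaries_by_dataset Named list (same names) of performance
#'   summaries covering the extra sites.
#' @param abundances Observed counts at the extra sites (`site`, `month`,
#'   `replicate`, `count`).
#' @param elevations Tibble `site`, `elevation`.
#' @return Tibble `dataset`, `mean_abs_pct_diff`, `elevation_slope`,
#'   `elevation_p`, `elevation_r2`; per-site differences as attribute
#'   `per_site`.
#' @export
spatial_validation <- function(models, summaries_by_dataset, abundances,
                               elevations) {
  obs <- dplyr::summarise(dplyr::group_by(as_tibble(abundances), .data$site),
                          observed = mean(.data$count), .groups = "drop")
  per_site <- list()
  rows <- lapply(names(models), function(ds) {
    pr <- predict_abundance(models[[ds]], summaries_by_dataset[[ds]])
    pr <- dplyr::summarise(dplyr::group_by(pr, .data$site),
                           predicted = mean(.data$predicted),
                           .groups = "drop")
    d <- dplyr::inner_join(obs, pr, by = "site")
    d <- dplyr::inner_join(d, as_tibble(elevations), by = "site")
    d$abs_pct_diff <- abs(d$predicted - d$observed) / d$observed * 100
    per_site[[ds]] <<- d
    efit <- lm(abs_pct_diff ~ elevation, data = d)
    esm <- summary(efit)
    tibble(dataset = ds,
           mean_abs_pct_diff = mean(d$abs_pct_diff),
           elevation_slope = unname(coef(efit)[2]),
           elevation_p = unname(esm$coefficients["elevation", "Pr(>|t|)"]),
           elevation_r2 = esm$r.squared)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "per_site") <- per_site
  out
}

#' Plain-text fit report mirroring the dataset-comparison table
#'
#' @param models Named list of [stepwise_aic()] results.
#' @return Data frame `dataset`, `model`, `aic`, `r_squared`.
#' @export
fit_report <- function(models) {
  dplyr::bind_rows(lapply(names(models), function(ds) {
    m <- models[[ds]]
    rhs <- if (length(m$selected_terms))
      paste(m$selected_terms, collapse = " + ") else "1"
    tibble(dataset = ds, model = paste("N ~", rhs),
           aic = m$aic, r_squared = m$r_squared)
  }))
}
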