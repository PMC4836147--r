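test_that("design matrix joins counts to summaries with the candidate set", {
  sm <- toy_summaries("station")
  ab <- simulate_abundances(sm, c(intercept = 80, S = 100), noise_sd = 5,
                            n_replicates = 6, seed = 1)
  dm <- build_design_matrix(sm, ab)
  expect_equal(nrow(dm), 4 * 12 * 6)
  expect_setequal(attr(dm, "candidates"),
                  c("S", "D", "F", "temp", "q1S", "q1D", "q1F", "q1temp",
                    "q3S", "q3D", "q3F", "q3temp"))
  # projection: candidate columns are copies of the summary fields
  row <- dm[dm$site == "Lowland 1" & dm$month == 4, ][1, ]
  src <- sm[sm$site == "Lowland 1" & sm$month == 4, ]
  expect_equal(row$S, src$S_mean)
  expect_equal(row$q3temp, src$temp_q3)
  # replicates share predictors within a site x month
  reps <- dm[dm$site == "Lowland 1" & dm$month == 4, ]
  expect_equal(length(unique(reps$q1F)), 1L)

  # climatology summaries expose means only
  smw <- toy_summaries("worldclim")
  dmw <- build_design_matrix(smw, simulate_abundances(
    smw, c(intercept = 80), noise_sd = 1, seed = 2))
  expect_setequal(attr(dmw, "candidates"), c("S", "D", "F", "temp"))

  # unmatched abundance rows error
  orphan <- dplyr::bind_rows(ab, tibble::tibble(site = "Nowhere", month = 1,
                                                replicate = 1, count = 5))
  expect_error(build_design_matrix(sm, orphan), "without a matching summary")
})

test_that("stepwise regression recovers a planted model at low noise", {
  sm <- toy_summaries("station")
  ab <- simulate_abundances(sm, c(intercept = 3, S = 2), noise_sd = 1e-6,
                            n_replicates = 6, seed = 3)
  # rounding to counts would swamp a 1e-6 noise floor; rebuild the exact
  # response from the generator's own linear predictor instead
  dm <- build_design_matrix(sm, ab)
  set.seed(3)
  dm$count <- 3 + 2 * dm$S + rnorm(nrow(dm), 0, 1e-8)
  # an all-but-exact fit makes stats warn about near-perfect models
  fit <- suppressWarnings(stepwise_aic(dm))
  expect_true("S" %in% fit$selected_terms)
  expect_equal(unname(fit$coefficients["(Intercept)"]), 3, tolerance = 1e-6)
  expect_equal(unname(fit$coefficients["S"]), 2, tolerance = 1e-6)
  expect_gte(fit$r_squared, 0.999)
})

test_that("stepwise never worsens AIC and beats the intercept-only model", {
  sm <- toy_summaries("worldclim")
  dm0 <- build_design_matrix(sm, simulate_abundances(
    sm, c(intercept = 50), noise_sd = 10, seed = 1))
  for (seed in 1:20) {
    set.seed(seed)
    dm0$count <- rnorm(nrow(dm0), 50, 10)  # pure-noise response
    full_fit <- lm(reformulate(attr(dm0, "candidates"), "count"), data = dm0)
    fit <- stepwise_aic(dm0)
    expect_lte(fit$aic, AIC(full_fit))
    null_r2 <- summary(lm(count ~ 1, data = dm0))$r.squared
    expect_gte(fit$r_squared, null_r2)
  }
})

test_that("stepwise agrees with exhaustive best-subset search", {
  # four weakly correlated candidates -> all 16 subsets enumerable
  cand <- c("S", "D", "F", "temp")
  subsets <- unlist(lapply(0:4, function(k) combn(cand, k, simplify = FALSE)),
                    recursive = FALSE)
  agree <- vapply(1:40, function(seed) {
    set.seed(seed)
    n <- 120
    dm <- tibble::tibble(S = rnorm(n), D = rnorm(n), F = rnorm(n),
                         temp = rnorm(n))
    truth <- sample(cand, 2)
    dm$count <- 100 + 40 * dm[[truth[1]]] + 25 * dm[[truth[2]]] +
      rnorm(n, 0, 10)
    attr(dm, "candidates") <- cand
    best <- subsets[[which.min(vapply(subsets, function(s) {
      f <- if (length(s)) reformulate(s, "count") else count ~ 1
      AIC(lm(f, data = dm))
    }, 0))]]
    setequal(stepwise_aic(dm)$selected_terms, best)
  }, logical(1))
  expect_gte(mean(agree), 0.95)
})

test_that("singular designs fail loudly with the collinear column named", {
  sm <- toy_summaries("worldclim")
  dm <- build_design_matrix(sm, simulate_abundances(
    sm, c(intercept = 10, S = 5), noise_sd = 1, seed = 4))
  dm$D <- 2 * dm$S + 1  # force exact collinearity
  expect_error(stepwise_aic(dm), "collinear")
})

test_that("predictions are the linear predictor, unclipped", {
  sm <- toy_summaries("station")
  # exact planted relation -> exact coefficients -> arithmetic predictions
  dm <- build_design_matrix(sm, simulate_abundances(
    sm, c(intercept = 3, S = 2), noise_sd = 0, n_replicates = 2, seed = 1))
  set.seed(2)
  dm$count <- 3 + 2 * dm$S + rnorm(nrow(dm), 0, 1e-8)
  fit <- suppressWarnings(stepwise_aic(dm))
  newdata <- sm[sm$site == "Highland 1", ]
  attr(newdata, "provenance") <- "station"
  pr <- predict_abundance(fit, newdata)
  expect_equal(pr$predicted, 3 + 2 * newdata$S_mean, tolerance = 1e-6)

  # intercept-only model predicts a constant
  dm2 <- dm
  dm2$count <- rep(7, nrow(dm2))
  f2 <- lm(count ~ 1, data = dm2)
  m2 <- structure(list(selected_terms = character(0), coefficients = coef(f2),
                       aic = AIC(f2), r_squared = 0, n_obs = nrow(dm2),
                       candidates = attr(dm, "candidates"), fit = f2),
                  class = "abundance_model")
  expect_equal(unique(predict_abundance(m2, newdata)$predicted), 7)

  # OLS residual zero-sum: training predictions average to the observed mean
  dm$count <- dm$count + rnorm(nrow(dm), 0, 5)
  fit3 <- stepwise_aic(dm)
  expect_equal(mean(predict(fit3$fit, newdata = dm)), mean(dm$count),
               tolerance = 1e-9)
})

test_that("temporal validation reports t-test, AIC and goodness of fit", {
  obs <- c(10, 12, 14, 16, 18, 20)
  tv <- temporal_validation(obs, obs)
  expect_equal(tv$t_p_value, 1)
  expect_equal(tv$r_squared, 1)

  # shifted predictions are detected with overwhelming confidence
  set.seed(1)
  o <- rnorm(60, 100, 5)
  tv2 <- temporal_validation(o, o + 50)
  expect_lt(tv2$t_p_value, 0.001)

  # R-squared equals the direct 1 - RSS/TSS formula
  p <- o + rnorm(60, 0, 3)
  tv3 <- temporal_validation(o, p)
  expect_equal(tv3$r_squared,
               1 - sum((o - p)^2) / sum((o - mean(o))^2), tolerance = 1e-12)
})

test_that("spatial validation measures percent error and its elevation trend", {
  sm <- toy_summaries("station")
  ab <- simulate_abundances(sm, c(intercept = 20, S = 150), noise_sd = 5,
                            n_replicates = 6, seed = 5)
  dm <- build_design_matrix(sm, ab)
  fit <- stepwise_aic(dm)

  # observed == predicted at every site -> zero error, zero slope
  pr <- predict_abundance(fit, sm)
  fake_obs <- tibble::tibble(site = pr$site, month = pr$month, replicate = 1,
                             count = pr$predicted)
  elevs <- tibble::tibble(site = unique(sm$site),
                          elevation = c(2713, 2727, 3280, 3152))
  sv <- spatial_validation(list(station = fit), list(station = sm),
                           fake_obs, elevs)
  expect_equal(sv$mean_abs_pct_diff, 0, tolerance = 1e-9)
  expect_equal(sv$elevation_slope, 0, tolerance = 1e-9)

  # hand arithmetic: observed 100 vs predicted 150 is a 50% difference
  per <- attr(sv, "per_site")$station
  one <- abs(150 - 100) / 100 * 100
  expect_equal(one, 50)

  # error proportional to elevation -> significant positive slope
  offs <- (elevs$elevation - 2600) / 1000 * 60  # up to ~+60% site bias
  biased <- dplyr::left_join(fake_obs, elevs, by = "site")
  biased$count <- biased$count * (1 + (biased$elevation - 2600) / 1000 * 0.6)
  sv2 <- spatial_validation(list(station = fit), list(station = sm),
                            biased[, c("site", "month", "replicate", "count")],
                            elevs)
  expect_gt(sv2$elevation_slope, 0)
  expect_lt(sv2$elevation_p, 0.05)
})

test_that("fit report mirrors the dataset comparison table", {
  sm <- toy_summaries("worldclim")
  dm <- build_design_matrix(sm, simulate_abundances(
    sm, c(intercept = 20, S = 150), noise_sd = 5, seed = 6))
  fit <- stepwise_aic(dm)
  rep_ <- fit_report(list(worldclim = fit))
  expect_equal(rep_$dataset, "worldclim")
  expect_match(rep_$model, "^N ~ ")
  expect_equal(rep_$aic, fit$aic)
})
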