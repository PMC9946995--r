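make_rate_panel <- function(score_fun, rain_fun = NULL, n_cells = 4,
                            years = 2000:2015) {
  set.seed(2)
  rain <- tidyr::expand_grid(cell_id = seq_len(n_cells), year = years) |>
    dplyr::mutate(rain_total = if (is.null(rain_fun)) {
      600 + stats::rnorm(dplyr::n(), sd = 50)
    } else {
      rain_fun(year)
    })
  scores <- dplyr::mutate(rain, row = cell_id, col = 1L,
                          bg_score = score_fun(year, rain_total))
  list(scores = dplyr::select(scores, "cell_id", "row", "col", "year",
                              "bg_score"),
       rain = rain)
}

test_that("a pure linear drift is recovered regardless of rainfall", {
  p <- make_rate_panel(function(y, r) 0.01 * (y - 2000))
  tm <- pixelwise_rate(p$scores, p$rain)
  expect_equal(tm$rate, rep(0.01, 4), tolerance = 1e-10)
  expect_true(all(tm$rain_adjusted))
})

test_that("a pure rainfall response leaves no long-term rate", {
  p <- make_rate_panel(function(y, r) -0.5 * (r - 600) / 100,
                       rain_fun = function(y) 600 + 80 * sin(y))
  tm <- pixelwise_rate(p$scores, p$rain)
  expect_equal(tm$rate, rep(0, 4), tolerance = 1e-10)
})

test_that("rates match a brute-force normal-equations solve", {
  set.seed(33)
  p <- make_rate_panel(function(y, r) stats::rnorm(length(y), sd = 0.1))
  tm <- pixelwise_rate(p$scores, p$rain)
  df <- dplyr::inner_join(p$scores, p$rain, by = c("cell_id", "year"))
  mid <- mean(range(df$year))
  for (cl in unique(df$cell_id)) {
    sub <- df[df$cell_id == cl, ]
    X <- cbind(1, sub$year - mid, sub$rain_total - mean(sub$rain_total))
    beta <- solve(t(X) %*% X, t(X) %*% sub$bg_score)
    expect_equal(tm$rate[tm$cell_id == cl], beta[2], tolerance = 1e-10)
  }
})

test_that("rates are equivariant under score shifts and added drift", {
  p <- make_rate_panel(function(y, r) 0.3 + stats::rnorm(length(y), sd = 0.05))
  base <- pixelwise_rate(p$scores, p$rain)
  shifted <- dplyr::mutate(p$scores, bg_score = bg_score + 5)
  expect_equal(pixelwise_rate(shifted, p$rain)$rate, base$rate,
               tolerance = 1e-10)
  drifted <- dplyr::mutate(p$scores, bg_score = bg_score + 0.02 * year)
  expect_equal(pixelwise_rate(drifted, p$rain)$rate, base$rate + 0.02,
               tolerance = 1e-10)
})

test_that("constant rainfall falls back to an unadjusted slope, flagged", {
  p <- make_rate_panel(function(y, r) 0.01 * y, rain_fun = function(y) 600)
  tm <- pixelwise_rate(p$scores, p$rain)
  expect_false(any(tm$rain_adjusted))
  expect_equal(tm$rate, rep(0.01, 4), tolerance = 1e-10)
})

test_that("cells with too few years have an undefined rate", {
  p <- make_rate_panel(function(y, r) 0.01 * y, years = 2000:2003)
  tm <- pixelwise_rate(p$scores, p$rain, min_years = 5)
  expect_true(all(is.na(tm$rate)))
})

test_that("noiseless planted coefficients are recovered exactly without a field", {
  d <- simulate_trend_data(rows = 12, cols = 12, field_sd = 0, nugget_sd = 0,
                           seed = 3)
  fit <- fit_spatial_model(d, control = spatial_control(spatial = FALSE))
  eff <- attr(d, "effects")
  est <- fit$coefficients
  expect_equal(est$estimate[est$term == "(Intercept)"], eff[["intercept"]],
               tolerance = 1e-8)
  expect_equal(est$estimate[est$term == "human"], eff[["human"]],
               tolerance = 1e-8)
  expect_equal(est$estimate[est$term == "rainfall"], eff[["rainfall"]],
               tolerance = 1e-8)
  expect_equal(est$estimate[est$term == "designationNP"], eff[["NP"]],
               tolerance = 1e-8)
})

test_that("without the spatial field the fit equals ordinary least squares", {
  d <- simulate_trend_data(rows = 15, cols = 15, seed = 5)
  fit <- fit_spatial_model(d, control = spatial_control(spatial = FALSE))
  lmfit <- stats::lm(rate ~ scale(human) + scale(rainfall) + scale(livestock) +
                       designation, data = d)
  expect_equal(unname(fit$coefficients$estimate), unname(stats::coef(lmfit)),
               tolerance = 1e-8)
})

test_that("doubling a planted effect doubles its estimate within interval width", {
  eff <- c(intercept = 0.621, human = 0.015, rainfall = -0.052,
           livestock = 0.015, CCRO = 0, NP = -0.04, WMA = -0.018)
  eff2 <- eff; eff2[["human"]] <- 2 * eff[["human"]]
  f1 <- fit_spatial_model(simulate_trend_data(rows = 24, cols = 24,
                                              effects = eff, seed = 7))
  f2 <- fit_spatial_model(simulate_trend_data(rows = 24, cols = 24,
                                              effects = eff2, seed = 7))
  h1 <- f1$coefficients[f1$coefficients$term == "human", ]
  h2 <- f2$coefficients[f2$coefficients$term == "human", ]
  expect_lt(abs(h2$estimate - 2 * h1$estimate), h2$upper - h2$lower)
})

test_that("the fitted hyperparameters track a planted spatial field", {
  d <- simulate_trend_data(rows = 24, cols = 24, field_sd = 0.03,
                           field_range = 4, nugget_sd = 0.01, seed = 11)
  fit <- fit_spatial_model(d)
  expect_gt(fit$sigma_u, fit$sigma_e)  # field dominates by construction
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(glance(fit)$n, 576)
})

test_that("observations at the predictive mean give PIT scores of exactly one half", {
  d <- simulate_trend_data(rows = 12, cols = 12, seed = 13)
  fit <- fit_spatial_model(d, control = spatial_control(spatial = FALSE))
  fit$y <- fit$fitted
  cal <- calibration_check(fit)
  expect_equal(unique(cal$pit$pit), 0.5)
})

test_that("PIT scores are near-uniform for data simulated from the fitted model", {
  d <- simulate_trend_data(rows = 24, cols = 24, seed = 17)
  fit <- fit_spatial_model(d)
  cal <- calibration_check(fit)
  # null distribution of the uniformity distance at this sample size
  set.seed(1)
  null_ks <- replicate(200, {
    as.numeric(suppressWarnings(stats::ks.test(stats::runif(fit$n),
                                               "punif"))$statistic)
  })
  expect_lt(cal$ks_distance, stats::quantile(null_ks, 0.95) * 1.5)
})

test_that("omitting a strong spatial field degrades calibration on average", {
  ks <- purrr::map_dfr(1:6, function(s) {
    d <- simulate_trend_data(rows = 40, cols = 40, field_sd = 0.03,
                             field_range = 8, nugget_sd = 0.01, seed = s)
    tibble::tibble(
      well = calibration_check(fit_spatial_model(d))$ks_distance,
      mis = calibration_check(
        fit_spatial_model(d, control = spatial_control(spatial = FALSE))
      )$ks_distance)
  })
  expect_gt(mean(ks$mis), mean(ks$well))
})
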