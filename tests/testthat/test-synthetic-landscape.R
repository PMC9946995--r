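test_that("shock years realise the configured rainfall deficit exactly (noiseless)", {
  cfg <- tiny_config(rain_sd_mm = 0, rain_cell_sd_mm = 0, rain_gradient_mm = 0,
                     rain_mean_mm = 600, shock_deficit = 0.5)
  totals <- rainfall_totals(simulate_rainfall(cfg))
  shock <- totals$rain_total[totals$year %in% cfg$shock_years]
  normal <- totals$rain_total[totals$year == 2008]
  expect_equal(unique(shock), 300)
  expect_equal(unique(normal), 600)
})

test_that("rainfall generation is deterministic under the seed", {
  cfg <- tiny_config(seed = 11)
  expect_identical(simulate_rainfall(cfg), simulate_rainfall(cfg))
  expect_false(identical(simulate_rainfall(cfg),
                         simulate_rainfall(tiny_config(seed = 12))))
})

test_that("yearly totals without shocks match the configured climatology", {
  cfg <- world_config(grid_rows = 7, grid_cols = 7, years = 2000:2020,
                      shock_years = integer(0), rain_mean_mm = 600,
                      rain_sd_mm = 60, rain_cell_sd_mm = 0,
                      rain_gradient_mm = 0, seed = 5)
  totals <- rainfall_totals(simulate_rainfall(cfg))
  totals <- totals[totals$year %in% cfg$years & totals$cell_id == 1, ]
  se <- 60 / sqrt(nrow(totals))
  expect_lt(abs(mean(totals$rain_total) - 600), 3 * se)
})

test_that("rainfall generation rejects an empty year list", {
  expect_error(world_config(years = integer(0)), "non-empty")
})

test_that("frozen dynamics keep cover at its baseline", {
  cfg <- dyn_config(2000:2004)
  truth <- make_truth(beta = 0.3, delta = 0, rho = 0)
  rain <- make_rainfall(c(500, 650, 580, 610, 640), 2000:2004)
  cover <- simulate_cover_dynamics(truth, rain, cfg)
  expect_equal(cover$b_true, rep(0.3, 5))
})

test_that("one drought step adds exactly delta times the anomaly magnitude", {
  cfg <- dyn_config(2000:2002)
  truth <- make_truth(beta = 0.3, delta = 0.1, rho = 0)
  rain <- make_rainfall(c(700, 600, 500), 2000:2002)
  anom <- rainfall_anomaly(rainfall_totals(rain))
  cover <- simulate_cover_dynamics(truth, rain, cfg)
  # year 2002 has the only negative anomaly; oracle recursion by hand
  expect_equal(cover$b_true[cover$year == 2001], 0.3)
  expect_equal(cover$b_true[cover$year == 2002],
               0.3 + 0.1 * abs(anom$anomaly[anom$year == 2002]))
})

test_that("full recovery with rho = 1 and unit anomaly returns to baseline", {
  cfg <- dyn_config(2000:2002)
  truth <- make_truth(beta = 0.3, delta = 0.1, rho = 1)
  # totals (500, 600, 700): anomalies exactly (-1, 0, +1)
  rain <- make_rainfall(c(500, 600, 700), 2000:2002)
  cover <- simulate_cover_dynamics(truth, rain, cfg)
  expect_equal(cover$b_true[cover$year == 2000], 0.4)  # shock of delta * 1
  expect_equal(cover$b_true[cover$year == 2001], 0.4)  # neutral year
  expect_equal(cover$b_true[cover$year == 2002], 0.3)  # full recovery
})

test_that("noiseless dynamics follow the documented update rule exactly", {
  cfg <- dyn_config(2000:2006, gamma = 1)
  truth <- make_truth(beta = c(0.2, 0.35), delta = c(0.08, 0.12),
                      rho = c(0.3, 0.8), human = c(10, 30),
                      livestock = c(50, 200), n = 2)
  totals <- c(520, 690, 430, 700, 610, 575, 655)
  rain <- make_rainfall(totals, 2000:2006)
  anom <- rainfall_anomaly(rainfall_totals(rain))
  cover <- simulate_cover_dynamics(truth, rain, cfg)
  for (i in 1:2) {
    b <- truth$beta[i]
    press <- cfg$w_human * truth$human[i] + cfg$w_livestock * truth$livestock[i]
    for (y in 2000:2006) {
      A <- anom$anomaly[anom$year == y]
      b <- min(1, max(0, b + truth$delta[i] * max(0, -A) -
                        truth$rho[i] * (b - truth$beta[i]) * max(0, A) + press))
      expect_equal(cover$b_true[cover$pixel_id == i & cover$year == y], b,
                   tolerance = 1e-12)
    }
  }
})

test_that("dynamics reject recovery rates outside the unit interval", {
  cfg <- dyn_config(2000:2001)
  truth <- make_truth(rho = 1.5)
  rain <- make_rainfall(c(500, 700), 2000:2001)
  expect_error(simulate_cover_dynamics(truth, rain, cfg), "rho")
})

test_that("pure bare ground renders as the soil endmember; cloud-free scenes are fully valid", {
  cfg <- tiny_config(reflectance_sd = 0, cloud_prob = 0)
  truth <- simulate_pixel_truth(cfg)
  cover <- tidyr::expand_grid(
    dplyr::select(truth, "pixel_id", "row", "col"), year = cfg$years) |>
    dplyr::mutate(b_true = 1)
  scenes <- render_scenes(cover, truth, cfg)
  sc <- scenes[[50]]
  expect_true(all(sc$valid))
  for (bn in names(cfg$soil)) {
    expect_equal(unique(as.vector(sc$bands[[bn]])), unname(cfg$soil[[bn]]))
  }
})

test_that("cloud invalidation rate matches the configured probability", {
  cfg <- world_config(grid_rows = 50, grid_cols = 50, years = 2019:2020,
                      shock_years = integer(0), scenes_per_year = 2,
                      cloud_prob = 0.1, seed = 2)
  w <- simulate_world(cfg)
  scenes <- render_scenes(w$cover, w$truth, cfg)
  inval <- 1 - mean(vapply(scenes, function(s) mean(s$valid), numeric(1)))
  n <- 50 * 50 * length(scenes)
  se <- sqrt(0.1 * 0.9 / n)
  expect_lt(abs(inval - 0.1), 3 * se)
})

test_that("rendered indices move monotonically with true bare ground", {
  cfg <- world_config(grid_rows = 5, grid_cols = 1, block = 1, years = 2020,
                      shock_years = integer(0), reflectance_sd = 0,
                      cloud_prob = 0)
  ladder <- c(0, 0.25, 0.5, 0.75, 1)
  truth <- make_truth(beta = 0.5, n = 5)
  cover <- tibble::tibble(pixel_id = 1:5, row = 1:5, col = 1L, year = 2020,
                          b_true = ladder)
  scenes <- render_scenes(cover, truth, cfg)
  series <- index_series(scenes, c("evi", "bsi", "msavi"))
  mean_by_pixel <- function(ix) rowMeans(series$values[[ix]][1:5, ])
  expect_true(all(diff(mean_by_pixel("bsi")) > 0))
  expect_true(all(diff(mean_by_pixel("evi")) < 0))
  expect_true(all(diff(mean_by_pixel("msavi")) < 0))
})

test_that("the whole generator is bit-identical under a repeated seed", {
  w1 <- simulate_world(tiny_config(seed = 9))
  w2 <- simulate_world(tiny_config(seed = 9))
  expect_identical(w1$rainfall, w2$rainfall)
  expect_identical(w1$truth, w2$truth)
  expect_identical(w1$cover, w2$cover)
})

test_that("stratification crosses rainfall, greenness and landcover bins", {
  set.seed(1)
  df <- tibble::tibble(rainfall = runif(200), greenness = runif(200),
                       landcover = rep(c("grassland", "woodland"), 100))
  st <- stratify_sites(df)
  expect_lte(nlevels(st$stratum), 8)
  expect_gt(nlevels(st$stratum), 1)
  # cells at opposite rainfall quantiles with identical other layers separate
  probe <- tibble::tibble(rainfall = stats::quantile(df$rainfall, c(0.1, 0.9)),
                          greenness = 0.5, landcover = "grassland")
  st2 <- stratify_sites(dplyr::bind_rows(df, probe))
  n <- nrow(st2)
  expect_false(st2$stratum[n - 1] == st2$stratum[n])
})

test_that("constant stratification layers collapse to a single bin with a warning", {
  df <- tibble::tibble(rainfall = 1, greenness = 1,
                       landcover = rep("grassland", 10))
  w <- testthat::capture_warnings(st <- stratify_sites(df))
  expect_true(all(grepl("single bin", w)) && length(w) == 2)
  expect_equal(nlevels(droplevels(st$stratum)), 1L)
})

test_that("survey measurement is exact at the boundary and unbiased in the mean", {
  cfg <- world_config(grid_rows = 112, grid_cols = 112, years = 2016,
                      shock_years = integer(0), seed = 4)
  truth <- simulate_pixel_truth(cfg)
  strata <- dplyr::mutate(dplyr::select(truth, "pixel_id", "row", "col"),
                          stratum = factor("all"))
  zero_cover <- tibble::tibble(pixel_id = truth$pixel_id, row = truth$row,
                               col = truth$col, year = 2016, b_true = 0)
  p0 <- sample_survey_plots(zero_cover, strata, 50, 2016, seed = 1)
  expect_true(all(p0$bare_points == 0))

  cover4 <- dplyr::mutate(zero_cover, b_true = 0.4)
  p4 <- sample_survey_plots(cover4, strata, 1000, 2016, seed = 2)
  se <- sqrt(0.4 * 0.6 / 100) / sqrt(1000)
  expect_lt(abs(mean(p4$bare_fraction) - 0.4), 3 * se)
})

test_that("plots allocate evenly across strata and never sit in adjacent pixels", {
  cfg <- tiny_config()
  truth <- simulate_pixel_truth(cfg)
  strata <- dplyr::mutate(
    dplyr::select(truth, "pixel_id", "row", "col"),
    stratum = factor(rep(c("a", "b", "c"), length.out = nrow(truth))))
  cover <- tibble::tibble(pixel_id = truth$pixel_id, row = truth$row,
                          col = truth$col, year = 2016, b_true = 0.2)
  plots <- sample_survey_plots(cover, strata, 9, 2016, seed = 3)
  expect_equal(unname(table(plots$stratum)[c("a", "b", "c")]),
               array(c(3L, 3L, 3L)), ignore_attr = TRUE)
  d <- as.matrix(stats::dist(plots[, c("row", "col")], method = "maximum"))
  diag(d) <- Inf
  expect_true(all(d > 1))
})

test_that("survey sampling fails cleanly when the request cannot be met", {
  truth <- make_truth(n = 4)
  truth$row <- c(1L, 1L, 2L, 2L); truth$col <- c(1L, 2L, 1L, 2L)
  strata <- dplyr::mutate(dplyr::select(truth, "pixel_id", "row", "col"),
                          stratum = factor("all"))
  cover <- tibble::tibble(pixel_id = truth$pixel_id, row = truth$row,
                          col = truth$col, year = 2016, b_true = 0.1)
  expect_error(sample_survey_plots(cover, strata, 3, 2016, seed = 1),
               "non-adjacent")
})
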