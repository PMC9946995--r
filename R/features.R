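# Per-pixel, per-year predictor features: index means, harmonic magnitude and
# phase, windowed annual rainfall, and standardization.

#' Harmonic regression over a focal year's seasonal window
#'
#' Fits, per pixel and index, ordinary least squares on the design
#' `[1, cos(2*pi*t), sin(2*pi*t)]` with `t` the fraction of the year of each
#' valid scene inside the focal seasonal window (November of the previous
#' year through October). Magnitude is `sqrt(a1^2 + b1^2)` and phase is
#' `atan2(b1, a1)` in `(-pi, pi]`, so a pure cosine peaking at the start of
#' the year has phase 0, and delaying a pure cosine by `dt` of a year
#' increases the phase by `2*pi*dt`. Pixels with fewer than `min_scenes` valid
#' observations are masked.
#'
#' @param series An `rw_index_series`.
#' @param focal_year Calendar year whose seasonal window is fitted.
#' @param min_scenes Minimum valid scenes per pixel (default 3, the number of
#'   coefficients).
#' @return A tibble `pixel_id`, `row`, `col`, `year`, `index`, `a0`, `a1`,
#'   `b1`, `magnitude`, `phase`, `n_scenes`.
#' @export
harmonic_fit <- function(series, focal_year, min_scenes = 3) {
  stopifnot(inherits(series, "rw_index_series"))
  win <- composite_window(focal_year)
  sel <- which(series$dates >= win["start"] & series$dates < win["end"])
  if (length(sel) == 0) {
    stop(sprintf("no scenes fall in the %d harmonic window", focal_year))
  }
  frac <- series$dates[sel] - floor(series$dates[sel] + 1e-9)
  A <- cbind(1, cos(2 * pi * frac), sin(2 * pi * frac))
  px <- pixel_ids(series$nr, series$nc)
  out <- purrr::map(names(series$values), function(ix) {
    Y <- series$values[[ix]][, sel, drop = FALSE]
    fit <- .harmonic_solve(Y, A, min_scenes)
    tibble::tibble(px, year = as.integer(focal_year), index = ix,
                   a0 = fit$a0, a1 = fit$a1, b1 = fit$b1,
                   magnitude = sqrt(fit$a1^2 + fit$b1^2),
                   phase = atan2(fit$b1, fit$a1),
                   n_scenes = fit$n)
  })
  dplyr::bind_rows(out)
}

# Vectorized per-pixel OLS with missing observations: accumulate the 3x3
# normal equations from the validity mask and solve by cofactor expansion.
.harmonic_solve <- function(Y, A, min_scenes) {
  M <- !is.na(Y)
  Y0 <- ifelse(M, Y, 0)
  Mn <- M * 1
  # unique entries of X'X per pixel (symmetric 3x3)
  s11 <- Mn %*% (A[, 1] * A[, 1]); s12 <- Mn %*% (A[, 1] * A[, 2])
  s13 <- Mn %*% (A[, 1] * A[, 3]); s22 <- Mn %*% (A[, 2] * A[, 2])
  s23 <- Mn %*% (A[, 2] * A[, 3]); s33 <- Mn %*% (A[, 3] * A[, 3])
  t1 <- Y0 %*% A[, 1]; t2 <- Y0 %*% A[, 2]; t3 <- Y0 %*% A[, 3]
  det <- s11 * (s22 * s33 - s23^2) - s12 * (s12 * s33 - s23 * s13) +
    s13 * (s12 * s23 - s22 * s13)
  # cofactors of the (symmetric) normal matrix
  c11 <- s22 * s33 - s23^2
  c12 <- -(s12 * s33 - s13 * s23)
  c13 <- s12 * s23 - s13 * s22
  c22 <- s11 * s33 - s13^2
  c23 <- -(s11 * s23 - s12 * s13)
  c33 <- s11 * s22 - s12^2
  a0 <- (c11 * t1 + c12 * t2 + c13 * t3) / det
  a1 <- (c12 * t1 + c22 * t2 + c23 * t3) / det
  b1 <- (c13 * t1 + c23 * t2 + c33 * t3) / det
  n <- rowSums(M)
  bad <- n < min_scenes | !is.finite(det) | abs(det) < 1e-12
  a0[bad] <- NA_real_; a1[bad] <- NA_real_; b1[bad] <- NA_real_
  list(a0 = as.vector(a0), a1 = as.vector(a1), b1 = as.vector(b1), n = n)
}

#' Windowed annual rainfall
#'
#' Sums monthly rainfall from May of the previous calendar year through the
#' end of April of the focal year. This accumulation window captures both the
#' previous rainy season and the severity of the intervening dry season, the
#' rainfall that shapes grass cover visible in the focal year.
#'
#' @param rainfall Monthly rainfall tibble (`cell_id`, `year`, `month`,
#'   `rain_mm`).
#' @param focal_year Focal calendar year.
#' @return A tibble `cell_id`, `year`, `rain_annual` (mm).
#' @export
annual_rainfall <- function(rainfall, focal_year) {
  sel <- dplyr::filter(rainfall,
    (.data$year == focal_year - 1 & .data$month >= 5) |
      (.data$year == focal_year & .data$month <= 4))
  counts <- dplyr::count(sel, .data$cell_id)
  if (nrow(counts) == 0 || any(counts$n != 12)) {
    stop(sprintf("monthly rainfall incomplete for the May %d - April %d window",
                 focal_year - 1, focal_year))
  }
  dplyr::summarise(sel, rain_annual = sum(.data$rain_mm), .by = "cell_id") |>
    dplyr::mutate(year = as.integer(focal_year), .after = "cell_id")
}

#' Assemble the per-pixel, per-year feature table
#'
#' Joins, for every pixel and focal year: the seasonal-window mean of each
#' index, the harmonic magnitude and phase of each index, and the May-April
#' annual rainfall of the pixel's rainfall cell - ten predictors when the
#' default three indices are used. Pixel-years with any missing predictor are
#' dropped with a message.
#'
#' @param series An `rw_index_series` (typically EVI, BSI, MSAVI).
#' @param rainfall Monthly rainfall tibble.
#' @param cell_map Tibble mapping `pixel_id` to `cell_id`.
#' @param years Focal years to assemble.
#' @return A tibble `pixel_id`, `row`, `col`, `year`, `<index>_mean`,
#'   `<index>_mag`, `<index>_phase`, `rain_annual`.
#' @export
build_feature_table <- function(series, rainfall, cell_map, years) {
  rows <- purrr::map(years, function(y) {
    comp <- annual_composite(series, y)
    harm <- harmonic_fit(series, y) |>
      dplyr::select("pixel_id", "year", "index", "magnitude", "phase") |>
      tidyr::pivot_wider(names_from = "index",
                         values_from = c("magnitude", "phase"),
                         names_glue = "{index}_{.value}")
    names(harm) <- sub("_magnitude$", "_mag", names(harm))
    rain <- annual_rainfall(rainfall, y)
    comp |>
      dplyr::left_join(harm, by = c("pixel_id", "year")) |>
      dplyr::left_join(dplyr::select(cell_map, "pixel_id", "cell_id"),
                       by = "pixel_id") |>
      dplyr::left_join(dplyr::select(rain, "cell_id", "year", "rain_annual"),
                       by = c("cell_id", "year")) |>
      dplyr::select(-"cell_id")
  })
  out <- dplyr::bind_rows(rows)
  pred <- setdiff(names(out), c("pixel_id", "row", "col", "year"))
  keep <- stats::complete.cases(out[, pred])
  if (any(!keep)) {
    message(sprintf("dropping %d of %d pixel-year rows with missing predictors",
                    sum(!keep), length(keep)))
  }
  out[keep, ]
}

#' Predictor columns of a feature table
#'
#' @param data A feature table.
#' @return Character vector of predictor column names.
#' @export
feature_predictors <- function(data) {
  setdiff(names(data), c("pixel_id", "row", "col", "year", "plot_id",
                         "stratum", "n_points", "bare_points", "bare_fraction",
                         "cell_id", "bg_log"))
}

#' Standardization statistics for predictors
#'
#' Computes per-column mean and sample standard deviation (n - 1 convention)
#' on a reference sample, typically the model's training rows only, so the
#' same statistics can be reused at prediction time.
#'
#' @param data Feature table providing the reference sample.
#' @param cols Predictor columns (default: all predictor columns).
#' @return A tibble `term`, `mean`, `sd`.
#' @export
feature_stats <- function(data, cols = feature_predictors(data)) {
  stats <- tibble::tibble(
    term = cols,
    mean = unname(vapply(cols, function(cl) mean(data[[cl]]), numeric(1))),
    sd = unname(vapply(cols, function(cl) stats::sd(data[[cl]]), numeric(1)))
  )
  bad <- stats$term[is.na(stats$sd) | stats$sd == 0]
  if (length(bad) > 0) {
    stop(sprintf("zero-variance predictor(s): %s", paste(bad, collapse = ", ")))
  }
  stats
}

#' Standardize predictors with stored statistics
#'
#' Applies `(x - mean) / sd` per predictor. When `stats` is `NULL` the
#' statistics are computed from `data` itself; otherwise the stored reference
#' statistics are used (never the new data's own moments), which is the
#' contract that keeps holdout and prediction rows untouched by training-time
#' scaling.
#'
#' @param data Feature table.
#' @param stats A `term`/`mean`/`sd` tibble from [feature_stats()], or `NULL`.
#' @return `data` with standardized predictor columns; the statistics used are
#'   attached as attribute `"feature_stats"`.
#' @export
standardize_features <- function(data, stats = NULL) {
  if (is.null(stats)) stats <- feature_stats(data)
  out <- data
  for (i in seq_len(nrow(stats))) {
    cl <- stats$term[i]
    out[[cl]] <- (out[[cl]] - stats$mean[i]) / stats$sd[i]
  }
  attr(out, "feature_stats") <- stats
  out
}
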