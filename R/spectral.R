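# Spectral indices, quality masking, gap filling and seasonal composites.

# Vectorized index kernels. Inputs are reflectances; NA propagates.
.ndvi <- function(nir, red) {
  den <- nir + red
  out <- (nir - red) / den
  out[!is.na(den) & den == 0] <- NA_real_
  out
}

.evi <- function(nir, red, blue) {
  den <- nir + 6 * red - 7.5 * blue + 1
  out <- 2.5 * (nir - red) / den
  out[!is.na(den) & abs(den) < 1e-10] <- NA_real_
  out
}

.bsi <- function(swir, red, nir, blue) {
  a <- swir + red; b <- nir + blue
  den <- a + b
  out <- (a - b) / den
  out[!is.na(den) & den == 0] <- NA_real_
  out
}

.msavi <- function(nir, red) {
  rad <- (2 * nir + 1)^2 - 8 * (nir - red)
  out <- (2 * nir + 1 - sqrt(pmax(rad, 0))) / 2
  out[!is.na(rad) & rad < 0] <- NA_real_
  out
}

.index_fun <- function(name) {
  switch(name,
    ndvi = function(b) .ndvi(b$nir, b$red),
    evi = function(b) .evi(b$nir, b$red, b$blue),
    bsi = function(b) .bsi(b$swir, b$red, b$nir, b$blue),
    msavi = function(b) .msavi(b$nir, b$red),
    stop(sprintf("unknown index '%s'", name))
  )
}

.apply_index <- function(data, index) {
  need <- switch(index, ndvi = c("nir", "red"), evi = c("nir", "red", "blue"),
                 bsi = c("swir", "red", "nir", "blue"), msavi = c("nir", "red"))
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    stop(sprintf("missing band column(s): %s", paste(miss, collapse = ", ")))
  }
  vals <- .index_fun(index)(data)
  if ("valid" %in% names(data)) vals[!data$valid] <- NA_real_
  dplyr::mutate(tibble::as_tibble(data), !!index := vals)
}

#' Spectral indices from reflectance bands
#'
#' Compute the Normalized Difference Vegetation Index (`(NIR - Red) /
#' (NIR + Red)`), the Enhanced Vegetation Index (`2.5 (NIR - Red) /
#' (NIR + 6 Red - 7.5 Blue + 1)`), a four-band Bare Soil Index
#' (`((SWIR + Red) - (NIR + Blue)) / ((SWIR + Red) + (NIR + Blue))`, higher =
#' barer) and the Modified Soil-Adjusted Vegetation Index
#' (`(2 NIR + 1 - sqrt((2 NIR + 1)^2 - 8 (NIR - Red))) / 2`). Pixels where the
#' formula is undefined (zero denominator, negative radicand) or where a
#' `valid` column is `FALSE` are returned as `NA` rather than erroring.
#'
#' @param data A data frame with lower-case reflectance band columns among
#'   `blue`, `red`, `nir`, `swir`, and optionally a logical `valid` column.
#' @return The input as a tibble with the index column appended.
#' @examples
#' compute_ndvi(tibble::tibble(nir = 0.5, red = 0.1))
#' @export
compute_ndvi <- function(data) .apply_index(data, "ndvi")

#' @rdname compute_ndvi
#' @export
compute_evi <- function(data) .apply_index(data, "evi")

#' @rdname compute_ndvi
#' @export
compute_bsi <- function(data) .apply_index(data, "bsi")

#' @rdname compute_ndvi
#' @export
compute_msavi <- function(data) .apply_index(data, "msavi")

#' Mask low-quality (cloudy) observations
#'
#' Invalidates every pixel whose cloud score is at or above the threshold;
#' only pixels with cloud score strictly below `threshold` percent are kept.
#'
#' @param x A data frame with a `valid` column, or an `rw_scene`.
#' @param cloud_score Per-pixel cloud score in `[0, 100]`: a numeric column
#'   name (data-frame method, default `"cloud_score"`) or a matrix/vector
#'   (scene method).
#' @param threshold Percent cloud-cover threshold (default 10).
#' @param ... Unused.
#' @return Same type as `x` with the validity mask updated.
#' @export
mask_low_quality <- function(x, cloud_score, threshold = 10, ...) {
  UseMethod("mask_low_quality")
}

.check_cloud_score <- function(score) {
  if (any(is.na(score)) || any(score < 0 | score > 100)) {
    stop("cloud scores must lie in [0, 100]")
  }
}

#' @rdname mask_low_quality
#' @export
mask_low_quality.data.frame <- function(x, cloud_score = "cloud_score",
                                        threshold = 10, ...) {
  score <- x[[cloud_score]]
  .check_cloud_score(score)
  x$valid <- (x$valid %||% TRUE) & (score < threshold)
  tibble::as_tibble(x)
}

#' @rdname mask_low_quality
#' @export
mask_low_quality.rw_scene <- function(x, cloud_score, threshold = 10, ...) {
  .check_cloud_score(cloud_score)
  x$valid <- x$valid & (matrix(cloud_score, x$nr, x$nc) < threshold)
  x
}

# --- index series over a scene list -----------------------------------------

#' Build per-pixel index time series from a list of scenes
#'
#' @param scenes A list of `rw_scene` objects (any date order; sorted
#'   internally).
#' @param indices Character vector among `"evi"`, `"bsi"`, `"msavi"`, `"ndvi"`.
#' @return An `rw_index_series`: per index a pixels-by-scenes matrix with `NA`
#'   at invalid observations, plus the scene dates and grid shape.
#' @export
index_series <- function(scenes, indices = c("evi", "bsi", "msavi")) {
  stopifnot(length(scenes) > 0)
  dates <- vapply(scenes, function(s) s$date, numeric(1))
  ord <- order(dates)
  scenes <- scenes[ord]; dates <- dates[ord]
  if (any(diff(dates) <= 0)) stop("scene dates must be strictly increasing")
  nr <- scenes[[1]]$nr; nc <- scenes[[1]]$nc
  npix <- nr * nc
  vals <- lapply(indices, function(ix) matrix(NA_real_, npix, length(scenes)))
  names(vals) <- indices
  valid <- matrix(NA, npix, length(scenes))
  for (k in seq_along(scenes)) {
    sc <- scenes[[k]]
    b <- lapply(sc$bands, as.vector)
    v <- as.vector(sc$valid)
    valid[, k] <- v
    for (ix in indices) {
      col <- .index_fun(ix)(b)
      col[!v] <- NA_real_
      vals[[ix]][, k] <- col
    }
  }
  structure(list(values = vals, dates = dates, valid = valid, nr = nr, nc = nc),
            class = "rw_index_series")
}

#' @export
print.rw_index_series <- function(x, ...) {
  cat(sprintf("<rw_index_series> %s; %d px x %d scenes (%.3f-%.3f)\n",
              paste(names(x$values), collapse = ", "),
              nrow(x$valid), length(x$dates), min(x$dates), max(x$dates)))
  invisible(x)
}

#' Fill short gaps in a time series by temporal interpolation
#'
#' Runs of one to three consecutive missing values are replaced by linear
#' interpolation (in time) between the flanking valid values; longer runs and
#' runs touching either boundary are left missing. Originally valid values are
#' never altered, and the operation is idempotent.
#'
#' @param x A numeric vector or an `rw_index_series`.
#' @param dates Observation times (vector method; defaults to equal spacing).
#' @param max_run Longest run length to fill (default 3).
#' @param ... Unused.
#' @return Same type as `x` with interior short gaps filled.
#' @examples
#' fill_gaps(c(1, NA, 3))
#' @export
fill_gaps <- function(x, ...) UseMethod("fill_gaps")

#' @rdname fill_gaps
#' @export
fill_gaps.numeric <- function(x, dates = seq_along(x), max_run = 3, ...) {
  as.numeric(zoo::na.approx(x, x = dates, maxgap = max_run, na.rm = FALSE))
}

#' @rdname fill_gaps
#' @export
fill_gaps.rw_index_series <- function(x, max_run = 3, ...) {
  x$values <- lapply(x$values, function(m) {
    t(zoo::na.approx(t(m), x = x$dates, maxgap = max_run, na.rm = FALSE))
  })
  x
}

#' Seasonal annual composite of an index series
#'
#' Averages each pixel's valid index observations over the seasonal window of
#' the focal year: November 1 of the previous year through October 31 of the
#' focal year (half-open on the following November 1). Pixels with no valid
#' observation in the window are `NA`.
#'
#' @param series An `rw_index_series`.
#' @param focal_year Calendar year of the composite.
#' @param statistic Summary statistic (only `"mean"` is supported).
#' @return A tibble `pixel_id`, `row`, `col`, `year`, then one column per
#'   index named `<index>_mean`.
#' @export
annual_composite <- function(series, focal_year, statistic = "mean") {
  stopifnot(inherits(series, "rw_index_series"))
  statistic <- match.arg(statistic, "mean")
  win <- composite_window(focal_year)
  sel <- series$dates >= win["start"] & series$dates < win["end"]
  if (!any(series$dates >= win["start"]) || !any(series$dates < win["end"])) {
    stop(sprintf("composite window for %d lies outside the scene series",
                 focal_year))
  }
  if (!any(sel)) {
    stop(sprintf("no scenes fall in the %d composite window", focal_year))
  }
  out <- pixel_ids(series$nr, series$nc)
  out$year <- as.integer(focal_year)
  for (ix in names(series$values)) {
    m <- series$values[[ix]][, sel, drop = FALSE]
    out[[paste0(ix, "_mean")]] <- rowMeans(m, na.rm = TRUE)
    out[[paste0(ix, "_mean")]][rowSums(!is.na(m)) == 0] <- NA_real_
  }
  out
}
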