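# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

clip01 <- function(x) pmin(1, pmax(0, x))

# Cumulative days before each month on a fixed 365-day (no-leap) calendar.
.month_cumdays <- c(0L, 31L, 59L, 90L, 120L, 151L, 181L, 212L, 243L, 273L, 304L, 334L)

#' Fraction of the year elapsed at the start of a calendar day
#'
#' Dates throughout the package are represented as `year + fraction`, with the
#' fraction computed on a fixed 365-day calendar (no leap days), so that window
#' boundaries such as "November 1" are unambiguous across years.
#'
#' @param month Month number (1-12).
#' @param day Day of month (defaults to 1).
#' @return Fraction of the year in `[0, 1)`.
#' @keywords internal
date_frac <- function(month, day = 1) {
  stopifnot(all(month >= 1 & month <= 12))
  (.month_cumdays[month] + day - 1) / 365
}

# Start of the seasonal compositing window for a focal year: Nov 1 of the
# previous year. The window is the half-open interval [start, start + 1),
# so Oct 31 of the focal year is the last day included.
composite_window <- function(focal_year) {
  start <- focal_year - 1 + date_frac(11, 1)
  c(start = start, end = start + 1)
}

# Smooth random field on an nr x nc grid: iid normals on a coarse lattice,
# bilinearly interpolated to the fine grid. `scale` is the lattice spacing in
# fine pixels; larger scale -> smoother field. Uses the current RNG stream.
smooth_field <- function(nr, nc, scale = 8) {
  cr <- max(2, ceiling(nr / scale) + 1)
  cc <- max(2, ceiling(nc / scale) + 1)
  coarse <- matrix(stats::rnorm(cr * cc), cr, cc)
  # positions of fine pixels on the coarse lattice
  ri <- (seq_len(nr) - 1) / max(1, nr - 1) * (cr - 1) + 1
  ci <- (seq_len(nc) - 1) / max(1, nc - 1) * (cc - 1) + 1
  r0 <- pmin(floor(ri), cr - 1); rw <- ri - r0
  c0 <- pmin(floor(ci), cc - 1); cw <- ci - c0
  f11 <- coarse[cbind(rep(r0, nc), rep(c0, each = nr))]
  f21 <- coarse[cbind(rep(r0 + 1, nc), rep(c0, each = nr))]
  f12 <- coarse[cbind(rep(r0, nc), rep(c0 + 1, each = nr))]
  f22 <- coarse[cbind(rep(r0 + 1, nc), rep(c0 + 1, each = nr))]
  rw <- rep(rw, nc); cw <- rep(cw, each = nr)
  vals <- f11 * (1 - rw) * (1 - cw) + f21 * rw * (1 - cw) +
    f12 * (1 - rw) * cw + f22 * rw * cw
  matrix(vals, nr, nc)
}

# Rescale a numeric vector to a target range; constant input maps to midpoint.
rescale_to <- function(x, lo, hi) {
  rng <- range(x)
  if (diff(rng) == 0) return(rep((lo + hi) / 2, length(x)))
  lo + (x - rng[1]) / diff(rng) * (hi - lo)
}

# Fixed offsets defining named substreams of the root seed, so each generator
# stage is independently reproducible.
.seed_offsets <- c(
  rainfall = 101L, truth = 202L, dynamics = 303L, scenes = 404L,
  survey = 505L, model = 606L, trend = 707L
)

substream_seed <- function(seed, stream) {
  offset <- .seed_offsets[[stream]]
  (as.integer(seed) * 1013L + offset) %% 2147483629L
}

# Median bootstrap CI (percentile). Uses the current RNG stream.
boot_median_ci <- function(x, n_boot = 1000, conf = 0.95) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(c(lo = NA_real_, hi = NA_real_))
  if (n_boot <= 0) return(c(lo = NA_real_, hi = NA_real_))
  meds <- vapply(seq_len(n_boot), function(i) {
    stats::median(x[sample.int(length(x), replace = TRUE)])
  }, numeric(1))
  alpha <- (1 - conf) / 2
  stats::quantile(meds, c(alpha, 1 - alpha), names = FALSE) |>
    stats::setNames(c("lo", "hi"))
}

# Pixel ids are row-major over the fine grid.
pixel_ids <- function(nr, nc) {
  tibble::tibble(
    pixel_id = seq_len(nr * nc),
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr)
  )
}
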