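# Synthetic savanna landscape: rainfall, pixel truth, latent bare-ground
# dynamics, rendered reflectance scenes, and point-intercept survey plots.

#' Simulate a gridded monthly rainfall series
#'
#' Generates rainfall for every coarse cell, covering one calendar year before
#' the first simulation year (so previous-year accumulation windows are always
#' computable). Each cell has a long-term mean that follows a west-east
#' gradient; yearly totals are the mean plus a regionally coherent
#' (landscape-wide) Gaussian year effect plus a smaller per-cell residual,
#' with shock (drought) years reduced by `shock_deficit` relative to the cell
#' mean before noise, and the year immediately after a drought boosted by
#' `post_shock_boost` (relief rains). Annual totals are split into months
#' with a fixed bimodal profile (short rains Nov-Jan, long rains Mar-May).
#'
#' @param config An [world_config()] object.
#' @return A tibble with columns `cell_id`, `cell_row`, `cell_col`, `year`,
#'   `month`, `rain_mm`.
#' @examples
#' rf <- simulate_rainfall(world_config(grid_rows = 14, grid_cols = 14))
#' dplyr::count(rf, year)
#' @export
simulate_rainfall <- function(config) {
  stopifnot(inherits(config, "rw_config"))
  if (length(config$years) == 0) stop("`years` must be non-empty")
  nr <- config$grid_rows %/% config$block
  nc <- config$grid_cols %/% config$block
  cells <- tibble::tibble(
    cell_id = seq_len(nr * nc),
    cell_row = rep(seq_len(nr), times = nc),
    cell_col = rep(seq_len(nc), each = nr)
  )
  years <- c(min(config$years) - 1L, config$years)
  set.seed(substream_seed(config$seed, "rainfall"))
  cell_mean <- config$rain_mean_mm +
    config$rain_gradient_mm * (cells$cell_col - (nc + 1) / 2) / max(1, nc - 1)
  year_eff <- stats::rnorm(length(years), sd = config$rain_sd_mm)
  cell_noise <- matrix(
    stats::rnorm(nrow(cells) * length(years), sd = config$rain_cell_sd_mm),
    nrow(cells), length(years))
  year_factor <- ifelse(years %in% config$shock_years, 1 - config$shock_deficit,
    ifelse((years - 1) %in% config$shock_years,
           1 + config$post_shock_boost, 1))
  totals <- outer(cell_mean, year_factor) +
    rep(year_eff, each = nrow(cells)) + cell_noise
  totals <- pmax(totals, 0)
  out <- tidyr::expand_grid(cells, year = years, month = 1:12)
  # expand_grid varies month fastest, then year, then cell
  idx <- cbind(rep(seq_len(nrow(cells)), each = length(years) * 12),
               rep(rep(seq_along(years), each = 12), times = nrow(cells)))
  out$rain_mm <- totals[idx] * .month_weights[out$month]
  out
}

#' Annual rainfall totals per cell
#'
#' @param rainfall Monthly rainfall tibble from [simulate_rainfall()].
#' @param period `"calendar"` (Jan-Dec totals) or `"nov_oct"` (November of the
#'   previous year through October, the seasonal compositing window).
#' @return A tibble `cell_id`, `cell_row`, `cell_col`, `year`, `rain_total`.
#' @export
rainfall_totals <- function(rainfall, period = c("calendar", "nov_oct")) {
  period <- match.arg(period)
  df <- rainfall
  if (period == "nov_oct") {
    df <- dplyr::mutate(df, year = .data$year + as.integer(.data$month >= 11))
    # the leading partial window (months of the pre-series year only) is dropped
    df <- dplyr::filter(df, .data$year <= max(rainfall$year))
    counts <- dplyr::count(df, .data$cell_id, .data$year)
    full <- counts$year[counts$n == 12]
    df <- dplyr::filter(df, .data$year %in% unique(full))
  }
  dplyr::summarise(df, rain_total = sum(.data$rain_mm),
                   .by = c("cell_id", "cell_row", "cell_col", "year"))
}

#' Standardized rainfall anomalies per cell
#'
#' Anomalies are standardized against each cell's mean and standard deviation
#' over the supplied reference years, giving a scale-free shock size.
#'
#' @param totals Output of [rainfall_totals()].
#' @param reference_years Years defining the per-cell climatology.
#' @return `totals` with an added `anomaly` column.
#' @export
rainfall_anomaly <- function(totals, reference_years = unique(totals$year)) {
  ref <- dplyr::filter(totals, .data$year %in% reference_years) |>
    dplyr::summarise(mu = mean(.data$rain_total),
                     sigma = stats::sd(.data$rain_total), .by = "cell_id")
  if (any(is.na(ref$sigma) | ref$sigma == 0)) {
    stop("rainfall anomaly undefined: constant series in at least one cell")
  }
  dplyr::left_join(totals, ref, by = "cell_id") |>
    dplyr::mutate(anomaly = (.data$rain_total - .data$mu) / .data$sigma) |>
    dplyr::select(-"mu", -"sigma")
}

# Land-use designation zones: fixed rectangular blocks so designations are
# spatially contiguous, as real protected areas are.
designation_zones <- function(row, col, nr, nc) {
  out <- rep("NONE", length(row))
  out[row <= 0.30 * nr & col <= 0.40 * nc] <- "NP"
  out[row > 0.70 * nr] <- "WMA"
  out[col > 0.75 * nc & row <= 0.50 * nr] <- "CCRO"
  factor(out, levels = c("NONE", "CCRO", "WMA", "NP"))
}

#' Simulate per-pixel ground truth
#'
#' Draws the latent properties of every fine-grid pixel: baseline bare-ground
#' fraction, drought susceptibility (inverse resistance), recovery rate,
#' phenology phase, human and livestock density, land-use designation and
#' land-cover class. Heterogeneity in susceptibility/recovery follows smooth
#' spatial fields so that degradation classes are spatially coherent, and is
#' routed by the scenario preset in `config`.
#'
#' @param config An [world_config()] object.
#' @return A tibble with one row per fine pixel: `pixel_id`, `row`, `col`,
#'   `cell_id`, `cell_row`, `cell_col`, `beta`, `delta`, `rho`, `phase`,
#'   `human`, `livestock`, `designation`, `landcover`.
#' @export
simulate_pixel_truth <- function(config) {
  stopifnot(inherits(config, "rw_config"))
  nr <- config$grid_rows; nc <- config$grid_cols
  set.seed(substream_seed(config$seed, "truth"))
  px <- pixel_ids(nr, nc)
  px$cell_row <- (px$row - 1L) %/% config$block + 1L
  px$cell_col <- (px$col - 1L) %/% config$block + 1L
  ncoarse_r <- nr %/% config$block
  px$cell_id <- (px$cell_col - 1L) * ncoarse_r + px$cell_row
  scale <- max(4, round(min(nr, nc) / 6))
  px$beta <- rescale_to(as.vector(smooth_field(nr, nc, scale)),
                        config$beta_range[1], config$beta_range[2])
  px$delta <- rescale_to(as.vector(smooth_field(nr, nc, scale)),
                         config$delta_range[1], config$delta_range[2])
  px$rho <- rescale_to(as.vector(smooth_field(nr, nc, scale)),
                       config$rho_range[1], config$rho_range[2])
  px$phase <- (0.25 + 0.05 * as.vector(smooth_field(nr, nc, scale))) %% 1
  px$human <- rescale_to(as.vector(smooth_field(nr, nc, scale)), 5, 35)
  px$livestock <- rescale_to(as.vector(smooth_field(nr, nc, scale)), 0, 250)
  px$designation <- designation_zones(px$row, px$col, nr, nc)
  px$landcover <- factor(
    ifelse(as.vector(smooth_field(nr, nc, scale * 2)) > 0, "woodland", "grassland"),
    levels = c("grassland", "woodland")
  )
  px
}

#' Simulate latent bare-ground cover dynamics
#'
#' Iterates the annual update rule for the true bare-ground fraction
#' `b[i, t]`. With `A[t]` the standardized rainfall anomaly of year `t` in the
#' pixel's rainfall cell:
#' \deqn{b_{i,t} = \mathrm{clip}_{[0,1]}\big(b_{i,t-1} + \delta_i \max(0, -A_t)
#'   - \rho_i (b_{i,t-1} - \beta_i) \max(0, A_t)
#'   + \gamma (w_h h_i + w_l l_i + w_d[d_i]) + \varepsilon_{i,t}\big)}
#' with \eqn{\varepsilon \sim N(0, \sigma_{dyn}^2)} and
#' \eqn{b_{i, y_0 - 1} = \beta_i}. Susceptibility \eqn{\delta_i} drives the
#' decline during drought shocks (loss of resistance); the recovery rate
#' \eqn{\rho_i} pulls the pixel back towards its baseline in wet years (loss
#' of recovery when small).
#'
#' @param truth Pixel truth from [simulate_pixel_truth()].
#' @param rainfall Monthly rainfall from [simulate_rainfall()].
#' @param config An [world_config()] object.
#' @return A tibble `pixel_id`, `row`, `col`, `year`, `b_true`.
#' @export
simulate_cover_dynamics <- function(truth, rainfall, config) {
  stopifnot(inherits(config, "rw_config"))
  if (any(truth$rho < 0 | truth$rho > 1)) {
    stop("recovery rate `rho` must lie in [0, 1]")
  }
  years <- config$years
  totals <- rainfall_totals(rainfall, "calendar")
  have <- sort(unique(totals$year))
  if (!all(years %in% have)) stop("rainfall series does not cover all years")
  anom <- rainfall_anomaly(dplyr::filter(totals, .data$year %in% years),
                           reference_years = years)
  # anomaly lookup: cells x years
  amat <- tidyr::pivot_wider(
    dplyr::select(anom, "cell_id", "year", "anomaly"),
    names_from = "year", values_from = "anomaly"
  )
  amat <- amat[order(amat$cell_id), ]
  a_by_year <- as.matrix(amat[, as.character(years)])
  cell_of <- match(truth$cell_id, amat$cell_id)

  set.seed(substream_seed(config$seed, "dynamics"))
  npix <- nrow(truth)
  pressure <- config$gamma * (config$w_human * truth$human +
    config$w_livestock * truth$livestock +
    unname(config$w_designation[as.character(truth$designation)]))
  b <- truth$beta
  out <- matrix(NA_real_, npix, length(years))
  for (t in seq_along(years)) {
    A <- a_by_year[cell_of, t]
    eps <- if (config$sigma_dyn > 0) {
      stats::rnorm(npix, sd = config$sigma_dyn)
    } else {
      numeric(npix)
    }
    b <- clip01(b + truth$delta * pmax(0, -A) -
                  truth$rho * (b - truth$beta) * pmax(0, A) +
                  pressure + eps)
    out[, t] <- b
  }
  tibble::tibble(
    pixel_id = rep(truth$pixel_id, times = length(years)),
    row = rep(truth$row, times = length(years)),
    col = rep(truth$col, times = length(years)),
    year = rep(years, each = npix),
    b_true = as.vector(out)
  )
}

# --- scene rendering ---------------------------------------------------------

new_scene <- function(date, bands, valid, nr, nc) {
  structure(list(date = date, year = floor(date + 1e-9),
                 frac = date - floor(date + 1e-9),
                 bands = bands, valid = valid, nr = nr, nc = nc),
            class = "rw_scene")
}

#' @export
print.rw_scene <- function(x, ...) {
  cat(sprintf("<rw_scene> date %.3f, %d x %d px, %.1f%% valid\n",
              x$date, x$nr, x$nc, 100 * mean(x$valid)))
  invisible(x)
}

#' Convert a scene to a tibble of per-pixel reflectances
#'
#' @param x An `rw_scene`.
#' @param ... Unused.
#' @return A tibble `pixel_id`, `row`, `col`, `date`, `blue`, `red`, `nir`,
#'   `swir`, `valid`.
#' @export
as_tibble.rw_scene <- function(x, ...) {
  px <- pixel_ids(x$nr, x$nc)
  tibble::tibble(
    px, date = x$date,
    blue = as.vector(x$bands$blue), red = as.vector(x$bands$red),
    nir = as.vector(x$bands$nir), swir = as.vector(x$bands$swir),
    valid = as.vector(x$valid)
  )
}

# Seasonal greenness multiplier: peaks at t = phase.
seasonal_greenness <- function(frac, phase) {
  0.5 * (1 + cos(2 * pi * (frac - phase)))
}

render_one_scene <- function(b, truth, frac, date, config) {
  nr <- config$grid_rows; nc <- config$grid_cols
  npix <- nr * nc
  g <- seasonal_greenness(frac, truth$phase)
  bands <- lapply(c(blue = "blue", red = "red", nir = "nir", swir = "swir"),
                  function(bn) {
    ref <- b * config$soil[[bn]] + (1 - b) * g * config$veg[[bn]]
    if (config$reflectance_sd > 0) {
      ref <- ref + stats::rnorm(npix, sd = config$reflectance_sd)
    }
    matrix(clip01(ref), nr, nc)
  })
  valid <- matrix(stats::runif(npix) >= config$cloud_prob, nr, nc)
  new_scene(date, bands, valid, nr, nc)
}

#' Render multi-band reflectance scenes from latent cover
#'
#' Per pixel, reflectance in each band is a linear soil/vegetation mixture
#' `b * soil + (1 - b) * g(t) * veg + noise`, with seasonal greenness
#' `g(t) = 0.5 * (1 + cos(2 * pi * (t - phase)))`, clipped to `[0, 1]`. Cloud
#' cover invalidates each pixel-scene independently with probability
#' `cloud_prob`. Scenes are rendered for every year of the series plus the
#' year before it (using the baseline cover), so that seasonal composites of
#' the first year have a full November-October window.
#'
#' @param cover Cover dynamics tibble from [simulate_cover_dynamics()].
#' @param truth Pixel truth from [simulate_pixel_truth()].
#' @param config An [world_config()] object.
#' @return A list of `rw_scene` objects in date order.
#' @export
render_scenes <- function(cover, truth, config) {
  stopifnot(inherits(config, "rw_config"))
  years <- c(min(config$years) - 1L, config$years)
  b_by_year <- c(
    list(truth$beta),
    lapply(config$years, function(y) {
      b <- cover$b_true[cover$year == y]
      if (length(b) != nrow(truth)) {
        stop(sprintf("cover does not define year %d for every pixel", y))
      }
      b
    })
  )
  set.seed(substream_seed(config$seed, "scenes"))
  scenes <- vector("list", length(years) * config$scenes_per_year)
  k <- 0
  for (yi in seq_along(years)) {
    for (s in seq_len(config$scenes_per_year)) {
      frac <- (s - 0.5) / config$scenes_per_year
      k <- k + 1
      scenes[[k]] <- render_one_scene(b_by_year[[yi]], truth, frac,
                                      years[yi] + frac, config)
    }
  }
  scenes
}

#' Simulate a complete synthetic world
#'
#' Convenience wrapper running rainfall, pixel truth and cover dynamics for a
#' configuration (scenes are rendered separately with [render_scenes()], which
#' is the expensive stage).
#'
#' @param config An [world_config()] object.
#' @return A list of class `rw_world` with elements `config`, `rainfall`,
#'   `truth`, `cover`.
#' @export
simulate_world <- function(config = world_config()) {
  rainfall <- simulate_rainfall(config)
  truth <- simulate_pixel_truth(config)
  cover <- simulate_cover_dynamics(truth, rainfall, config)
  structure(list(config = config, rainfall = rainfall, truth = truth,
                 cover = cover), class = "rw_world")
}

#' @export
print.rw_world <- function(x, ...) {
  print(x$config)
  cat(sprintf("  %d pixels x %d years of latent cover\n",
              nrow(x$truth), length(x$config$years)))
  invisible(x)
}

# --- survey design -----------------------------------------------------------

#' Stratify sites by rainfall, greenness and land cover
#'
#' Builds survey strata as the cross-product of quantile-binned rainfall,
#' quantile-binned greenness (e.g. mean annual NDVI) and the land-cover class,
#' so that field sampling spans the landscape's environmental gradients.
#'
#' @param layers A data frame with one row per site/pixel containing columns
#'   `rainfall`, `greenness` and `landcover` (any id columns are carried
#'   through).
#' @param rain_bins,green_bins Number of quantile bins (default 2 each).
#' @return `layers` with an added `stratum` factor.
#' @examples
#' df <- tibble::tibble(rainfall = runif(20), greenness = runif(20),
#'                      landcover = rep(c("grassland", "woodland"), 10))
#' table(stratify_sites(df)$stratum)
#' @export
stratify_sites <- function(layers, rain_bins = 2, green_bins = 2) {
  stopifnot(all(c("rainfall", "greenness", "landcover") %in% names(layers)))
  qbin <- function(x, bins, label) {
    brk <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                                  na.rm = TRUE))
    if (length(brk) < 2) {
      warning(sprintf("constant %s layer: using a single bin", label))
      return(rep(1L, length(x)))
    }
    as.integer(cut(x, breaks = brk, include.lowest = TRUE, labels = FALSE))
  }
  rb <- qbin(layers$rainfall, rain_bins, "rainfall")
  gb <- qbin(layers$greenness, green_bins, "greenness")
  dplyr::mutate(tibble::as_tibble(layers),
                stratum = factor(sprintf("R%d.G%d.%s", rb, gb,
                                         as.character(layers$landcover))))
}

#' Sample point-intercept survey plots
#'
#' Allocates plots evenly across strata, excludes neighbouring pixels (no two
#' plots within one pixel of each other, in the 8-neighbour sense), and
#' simulates the point-intercept measurement: out of `n_points` points per
#' plot, the number falling on bare ground is Binomial(`n_points`, true bare
#' fraction at the plot's pixel and survey year).
#'
#' @param b_true Cover tibble (`pixel_id`, `row`, `col`, `year`, `b_true`).
#' @param strata Tibble with `pixel_id`, `row`, `col`, `stratum` per pixel.
#' @param n_plots Total number of plots (split as evenly as possible across
#'   survey years), or a vector with one count per element of `years`.
#' @param years Survey years.
#' @param seed Integer seed for site selection and measurement.
#' @param n_points Point-intercept points per plot (default 100).
#' @return A tibble `plot_id`, `pixel_id`, `row`, `col`, `stratum`, `year`,
#'   `n_points`, `bare_points`, `bare_fraction`.
#' @export
sample_survey_plots <- function(b_true, strata, n_plots, years, seed,
                                n_points = 100) {
  if (length(n_plots) == 1) {
    base <- length(years)
    n_per_year <- rep(n_plots %/% base, base)
    extra <- n_plots %% base
    if (extra > 0) n_per_year[seq_len(extra)] <- n_per_year[seq_len(extra)] + 1
  } else {
    stopifnot(length(n_plots) == length(years))
    n_per_year <- n_plots
  }
  total <- sum(n_per_year)
  set.seed(seed)
  strata <- dplyr::arrange(strata, .data$pixel_id)
  labs <- sort(unique(as.character(strata$stratum)))
  quota <- rep(total %/% length(labs), length(labs))
  extra <- total %% length(labs)
  if (extra > 0) quota[seq_len(extra)] <- quota[seq_len(extra)] + 1
  nr <- max(strata$row); nc <- max(strata$col)
  blocked <- matrix(FALSE, nr, nc)
  chosen <- integer(0)
  for (i in seq_along(labs)) {
    cand <- strata[as.character(strata$stratum) == labs[i], ]
    cand <- cand[sample.int(nrow(cand)), ]
    got <- 0; j <- 1
    while (got < quota[i] && j <= nrow(cand)) {
      r <- cand$row[j]; cl <- cand$col[j]
      if (!blocked[r, cl]) {
        chosen <- c(chosen, cand$pixel_id[j])
        got <- got + 1
        rr <- max(1, r - 1):min(nr, r + 1)
        cc <- max(1, cl - 1):min(nc, cl + 1)
        blocked[rr, cc] <- TRUE
      }
      j <- j + 1
    }
    if (got < quota[i]) {
      stop(sprintf(
        "stratum %s has too few non-adjacent pixels (%d needed, %d placed)",
        labs[i], quota[i], got))
    }
  }
  year_vec <- sample(rep(years, times = n_per_year))
  plots <- strata[match(chosen, strata$pixel_id),
                  c("pixel_id", "row", "col", "stratum")]
  plots$year <- year_vec
  key_b <- paste(b_true$pixel_id, b_true$year)
  bt <- b_true$b_true[match(paste(plots$pixel_id, plots$year), key_b)]
  if (anyNA(bt)) stop("b_true does not cover all plot pixel-years")
  plots$n_points <- as.integer(n_points)
  plots$bare_points <- stats::rbinom(nrow(plots), n_points, bt)
  plots$bare_fraction <- plots$bare_points / n_points
  dplyr::mutate(tibble::as_tibble(plots),
                plot_id = dplyr::row_number(), .before = 1)
}
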