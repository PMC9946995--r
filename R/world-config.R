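#' Configuration for a synthetic savanna landscape
#'
#' Defines every knob of the synthetic world: the fine pixel grid (nominally
#' 30 m pixels), the year range, sub-annual scene sampling, drought shock
#' years, the latent cover dynamics (resistance/recovery parameters and
#' anthropogenic pressure effects), rainfall climatology, scene rendering
#' noise and cloud probability, and the field-survey design.
#'
#' Two scenario presets control where heterogeneity lives:
#' \describe{
#'   \item{`"loss_of_resistance"`}{drought susceptibility varies across the
#'     landscape while the recovery rate is constant, so pixels that end up
#'     degraded got there by declining more during shocks.}
#'   \item{`"loss_of_recovery"`}{susceptibility is constant and the recovery
#'     rate varies, so degraded pixels got there by failing to bounce back.}
#' }
#'
#' @param grid_rows,grid_cols Fine-grid dimensions in pixels.
#' @param years Ordered integer vector of calendar years.
#' @param scenes_per_year Number of reflectance scenes rendered per year.
#' @param seed Integer root seed; all generator stages draw from named
#'   substreams of it.
#' @param shock_years Subset of `years` rendered as drought years.
#' @param shock_deficit Fractional rainfall deficit in shock years (0.5 means
#'   roughly 50 percent below the cell's long-term mean).
#' @param post_shock_boost Fractional rainfall surplus in the year following
#'   a drought (default 0.2): the regional climatology swings wet after
#'   drought phases, which is what makes post-shock recovery observable.
#' @param rain_mean_mm,rain_sd_mm,rain_cell_sd_mm,rain_gradient_mm Long-term
#'   mean annual rainfall; inter-annual standard deviation of the
#'   landscape-wide (regionally coherent) year effect; standard deviation of
#'   the per-cell residual around it; and the west-east range of the spatial
#'   rainfall gradient (all mm).
#' @param block Fine pixels per coarse-cell side (7 x 30 m = 210 m nominal).
#' @param preset Scenario preset, see Details.
#' @param beta_range Range of baseline bare-ground fraction across pixels.
#' @param delta_range Range of drought susceptibility (bare-ground increase
#'   per unit negative rainfall anomaly); collapsed to its midpoint under the
#'   `"loss_of_recovery"` preset.
#' @param rho_range Range of the recovery rate in `[0, 1]` (fraction of the
#'   displacement from baseline removed per unit positive rainfall anomaly);
#'   collapsed to its midpoint under the `"loss_of_resistance"` preset.
#' @param gamma Scale applied to the anthropogenic pressure term.
#' @param w_human,w_livestock Pressure weights per person/km2 and per TLU/km2.
#' @param w_designation Named additive pressure offsets for the land-use
#'   designations `NONE`, `CCRO`, `WMA`, `NP`.
#' @param sigma_dyn Standard deviation of the annual dynamics noise.
#' @param reflectance_sd Standard deviation of reflectance noise per band.
#' @param cloud_prob Per pixel-scene probability of cloud invalidation.
#' @param soil,veg Endmember reflectance spectra, named `blue/red/nir/swir`,
#'   all in `[0, 1]`.
#' @param survey_years Years in which field surveys take place.
#' @param n_plots Plots per survey year (same order as `survey_years`).
#' @param stratify_year Year whose greenness is used for survey stratification.
#'
#' @return An object of class `rw_config` (a named list).
#' @examples
#' cfg <- world_config(grid_rows = 28, grid_cols = 28)
#' cfg$shock_years
#' @export
world_config <- function(grid_rows = 168, grid_cols = 168,
                         years = 2000:2020,
                         scenes_per_year = 12,
                         seed = 1,
                         shock_years = c(2002, 2006, 2011, 2016),
                         shock_deficit = 0.5,
                         post_shock_boost = 0.2,
                         rain_mean_mm = 600,
                         rain_sd_mm = 60,
                         rain_cell_sd_mm = 20,
                         rain_gradient_mm = 200,
                         block = 7,
                         preset = c("loss_of_resistance", "loss_of_recovery"),
                         beta_range = c(0.2, 0.3),
                         delta_range = c(0.02, 0.14),
                         rho_range = c(0.05, 0.9),
                         gamma = 1,
                         w_human = 1e-5,
                         w_livestock = 2e-6,
                         w_designation = c(NONE = 0, CCRO = 0, WMA = -2e-4, NP = -4e-4),
                         sigma_dyn = 0.02,
                         reflectance_sd = 0.01,
                         cloud_prob = 0.15,
                         soil = c(blue = 0.12, red = 0.22, nir = 0.28, swir = 0.34),
                         veg = c(blue = 0.04, red = 0.05, nir = 0.45, swir = 0.20),
                         survey_years = c(2016, 2018),
                         n_plots = c(208, 48),
                         stratify_year = 2015) {
  preset <- match.arg(preset)
  if (length(years) == 0) stop("`years` must be a non-empty vector of calendar years")
  years <- sort(unique(as.integer(years)))
  if (!all(shock_years %in% years)) {
    stop("`shock_years` must be a subset of `years`")
  }
  if (cloud_prob < 0 || cloud_prob > 1) stop("`cloud_prob` must be in [0, 1]")
  if (shock_deficit < 0 || shock_deficit > 1) stop("`shock_deficit` must be in [0, 1]")
  if (post_shock_boost < 0) stop("`post_shock_boost` must be non-negative")
  if (any(c(rain_sd_mm, rain_cell_sd_mm, sigma_dyn, reflectance_sd) < 0)) {
    stop("noise scales must be non-negative")
  }
  if (any(rho_range < 0 | rho_range > 1)) stop("`rho_range` must lie in [0, 1]")
  if (any(delta_range < 0)) stop("`delta_range` must be non-negative")
  if (any(soil < 0 | soil > 1) || any(veg < 0 | veg > 1)) {
    stop("endmember spectra must lie in [0, 1]")
  }
  if (length(n_plots) != length(survey_years)) {
    stop("`n_plots` must have one entry per survey year")
  }
  # Presets: heterogeneity lives in exactly one of (delta, rho).
  if (preset == "loss_of_resistance") {
    rho_range <- rep(mean(rho_range), 2)
  } else {
    delta_range <- rep(mean(delta_range), 2)
  }
  structure(list(
    grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
    years = years, scenes_per_year = as.integer(scenes_per_year),
    seed = as.integer(seed), shock_years = as.integer(shock_years),
    shock_deficit = shock_deficit, post_shock_boost = post_shock_boost,
    rain_mean_mm = rain_mean_mm,
    rain_sd_mm = rain_sd_mm, rain_cell_sd_mm = rain_cell_sd_mm,
    rain_gradient_mm = rain_gradient_mm,
    block = as.integer(block), preset = preset,
    beta_range = beta_range, delta_range = delta_range, rho_range = rho_range,
    gamma = gamma, w_human = w_human, w_livestock = w_livestock,
    w_designation = w_designation, sigma_dyn = sigma_dyn,
    reflectance_sd = reflectance_sd, cloud_prob = cloud_prob,
    soil = soil, veg = veg,
    survey_years = as.integer(survey_years), n_plots = as.integer(n_plots),
    stratify_year = as.integer(stratify_year)
  ), class = "rw_config")
}

#' @export
print.rw_config <- function(x, ...) {
  cat("<rw_config>\n")
  cat(sprintf("  fine grid: %d x %d (block %d -> %d x %d coarse)\n",
              x$grid_rows, x$grid_cols, x$block,
              x$grid_rows %/% x$block, x$grid_cols %/% x$block))
  cat(sprintf("  years: %d-%d, %d scenes/year, shocks: %s\n",
              min(x$years), max(x$years), x$scenes_per_year,
              paste(x$shock_years, collapse = ", ")))
  cat(sprintf("  preset: %s, seed %d\n", x$preset, x$seed))
  invisible(x)
}

# Monthly split of annual rainfall: bimodal wet seasons (Nov-Jan short rains,
# Mar-May long rains), matching the region's climatology. Sums to 1.
.month_weights <- c(0.14, 0.05, 0.12, 0.14, 0.08, 0.02,
                    0.01, 0.01, 0.02, 0.04, 0.17, 0.20)
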