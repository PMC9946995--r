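# Shared fixtures built in code.

# Small world: 28 x 28 fine pixels -> 4 x 4 coarse cells.
tiny_config <- function(seed = 1, ...) {
  world_config(grid_rows = 28, grid_cols = 28, seed = seed, ...)
}

# Medium world for scenario checks: 84 x 84 fine -> 12 x 12 coarse.
mid_config <- function(seed = 1, ...) {
  world_config(grid_rows = 84, grid_cols = 84, seed = seed, ...)
}

# Coarse, normalized score series straight from the latent cover truth.
truth_score_series <- function(world) {
  coarse <- aggregate_to_coarse(
    dplyr::rename(world$cover, bg_score = b_true), "bg_score",
    world$config$block)
  normalize_scores(coarse, "bg_score")
}

# Build an rw_index_series by hand from a pixels x scenes value matrix.
make_series <- function(values, dates, nr = NULL, nc = 1, index = "evi") {
  values <- as.matrix(values)
  if (is.null(nr)) nr <- nrow(values)
  structure(list(values = stats::setNames(list(values), index),
                 dates = dates, valid = !is.na(values), nr = nr, nc = nc),
            class = "rw_index_series")
}

# Monthly rainfall table realising given calendar-year totals for one cell.
make_rainfall <- function(totals, years, cell_id = 1L) {
  tibble::tibble(
    cell_id = cell_id, cell_row = 1L, cell_col = 1L,
    year = rep(years, each = 12), month = rep(1:12, length(years)),
    rain_mm = rep(totals / 12, each = 12)
  )
}

# Single-pixel truth table with explicit dynamics parameters.
make_truth <- function(beta = 0.3, delta = 0, rho = 0, human = 0,
                       livestock = 0, designation = "NONE", n = 1) {
  tibble::tibble(
    pixel_id = seq_len(n), row = seq_len(n), col = 1L, cell_id = 1L,
    cell_row = 1L, cell_col = 1L,
    beta = beta, delta = delta, rho = rho, phase = 0.25,
    human = human, livestock = livestock,
    designation = factor(designation, levels = c("NONE", "CCRO", "WMA", "NP")),
    landcover = factor("grassland", levels = c("grassland", "woodland"))
  )
}

# Config whose years/shocks can be paired with hand-made rainfall.
dyn_config <- function(years, shock_years = integer(0), sigma_dyn = 0,
                       gamma = 0, ...) {
  world_config(grid_rows = 7, grid_cols = 7, years = years,
               shock_years = shock_years, sigma_dyn = sigma_dyn,
               gamma = gamma, ...)
}
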