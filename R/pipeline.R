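# End-to-end orchestration: simulate -> features -> train -> predict ->
# resilience -> trend, with plain-text artifacts and a hashed manifest.

#' Pipeline configuration
#'
#' Bundles the world configuration with the analysis settings of every
#' downstream stage.
#'
#' @param world An [world_config()] object.
#' @param indices Spectral indices used as predictors.
#' @param reference_year Scaling reference year for the bare-ground series.
#' @param final_years Tertile basis years.
#' @param k_shocks Number of shock years to detect.
#' @param alpha,min_effect,guard Verdict decision parameters.
#' @param n_boot Bootstrap resamples for summary CIs.
#' @param algorithms Candidate regressors for the bare-ground index.
#' @return A list of class `rw_pipeline_config`.
#' @export
pipeline_config <- function(world = world_config(),
                            indices = c("evi", "bsi", "msavi"),
                            reference_year = 2016,
                            final_years = c(2018, 2019, 2020),
                            k_shocks = 4, alpha = 0.05, min_effect = 0.01,
                            guard = 0.01, n_boot = 200,
                            algorithms = c("rf", "svr", "gbt")) {
  structure(list(world = world, indices = indices,
                 reference_year = reference_year, final_years = final_years,
                 k_shocks = k_shocks, alpha = alpha, min_effect = min_effect,
                 guard = guard, n_boot = n_boot, algorithms = algorithms),
            class = "rw_pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config An `rw_pipeline_config`.
#' @param path YAML file path.
#' @return `read_pipeline_config()` returns an `rw_pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  lst <- unclass(config)
  lst$world <- unclass(lst$world)
  # named vectors become YAML maps so names survive the round trip
  for (f in c("soil", "veg", "w_designation")) {
    lst$world[[f]] <- as.list(lst$world[[f]])
  }
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  lst <- yaml::read_yaml(path)
  wl <- lst$world
  wl$w_designation <- unlist(wl$w_designation)
  wl$soil <- unlist(wl$soil)
  wl$veg <- unlist(wl$veg)
  world <- do.call(world_config, wl[setdiff(names(wl), "preset")] |>
                     c(list(preset = wl$preset)))
  do.call(pipeline_config, c(list(world = world),
                             lst[setdiff(names(lst), "world")]))
}

.mode_level <- function(x) {
  tb <- sort(table(x), decreasing = TRUE)
  names(tb)[1]
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order, writing every artifact as a
#' plain-text file under `outdir` and returning a manifest with an MD5 hash
#' per artifact. With an identical configuration (and its seed) the
#' deterministic artifacts hash identically across reruns. Later stages read
#' the artifacts of earlier stages from `outdir` when those stages are not in
#' `stages` for this run; a missing upstream artifact raises an error naming
#' the stage to rerun. (The trained model object itself is not a text
#' artifact, so `"predict"` must run together with `"train"`.)
#'
#' @param config An [pipeline_config()] object.
#' @param outdir Output directory (created if needed).
#' @param stages Stages to execute, a subset of `simulate`, `features`,
#'   `train`, `predict`, `resilience`, `trend` (order fixed internally).
#' @param quiet Suppress progress messages.
#' @return A list of class `rw_manifest`: `artifacts` (tibble with `artifact`,
#'   `stage`, `md5`), `outdir`, `stages`, `timings` (seconds per stage).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir,
                         stages = c("simulate", "features", "train", "predict",
                                    "resilience", "trend"),
                         quiet = FALSE) {
  all_stages <- c("simulate", "features", "train", "predict", "resilience",
                  "trend")
  stages <- all_stages[all_stages %in% stages]
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wc <- config$world
  say <- function(...) if (!quiet) message(sprintf(...))
  mem <- new.env(parent = emptyenv())
  arts <- list()
  timings <- c()
  note <- function(stage, files) {
    arts[[length(arts) + 1]] <<- tibble::tibble(artifact = files, stage = stage)
  }
  put <- function(name, obj, file = NULL, stage = NULL) {
    assign(name, obj, envir = mem)
    if (!is.null(file)) {
      utils::write.csv(obj, file.path(outdir, file), row.names = FALSE)
      note(stage, file)
    }
  }
  get_obj <- function(name, file, stage, reader = utils::read.csv) {
    if (exists(name, envir = mem)) return(get(name, envir = mem))
    path <- file.path(outdir, file)
    if (!file.exists(path)) {
      stop(sprintf("missing upstream artifact '%s': rerun stage '%s'",
                   file, stage))
    }
    tibble::as_tibble(reader(path))
  }
  run_stage <- function(stage, fn) {
    if (!stage %in% stages) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    say("[%s] running", stage)
    fn()
    timings[[stage]] <<- proc.time()[["elapsed"]] - t0
  }

  write_pipeline_config(config, file.path(outdir, "config.yaml"))
  note("config", "config.yaml")

  run_stage("simulate", function() {
    world <- simulate_world(wc)
    put("rainfall", world$rainfall, "rainfall.csv", "simulate")
    put("truth", world$truth, "truth.csv", "simulate")
    put("cover", world$cover, "cover.csv", "simulate")
  })

  run_stage("features", function() {
    truth <- get_obj("truth", "truth.csv", "simulate")
    rainfall <- get_obj("rainfall", "rainfall.csv", "simulate")
    cover <- get_obj("cover", "cover.csv", "simulate")
    scenes <- render_scenes(cover, truth, wc)
    series <- index_series(scenes, unique(c(config$indices, "ndvi")))
    rm(scenes)
    series <- fill_gaps(series)
    greenness <- annual_composite(
      structure(list(values = series$values["ndvi"], dates = series$dates,
                     valid = series$valid, nr = series$nr, nc = series$nc),
                class = "rw_index_series"),
      wc$stratify_year)
    series$values <- series$values[config$indices]
    features <- build_feature_table(series, rainfall, truth, wc$years)
    put("greenness", greenness, "greenness.csv", "features")
    put("features", features, "features.csv", "features")
  })

  run_stage("train", function() {
    truth <- get_obj("truth", "truth.csv", "simulate")
    rainfall <- get_obj("rainfall", "rainfall.csv", "simulate")
    cover <- get_obj("cover", "cover.csv", "simulate")
    features <- get_obj("features", "features.csv", "features")
    greenness <- get_obj("greenness", "greenness.csv", "features")
    rain_mean <- rainfall_totals(rainfall, "calendar") |>
      dplyr::summarise(rainfall = mean(.data$rain_total), .by = "cell_id")
    layers <- truth |>
      dplyr::left_join(rain_mean, by = "cell_id") |>
      dplyr::left_join(dplyr::select(greenness, "pixel_id",
                                     greenness = "ndvi_mean"),
                       by = "pixel_id")
    strata <- stratify_sites(layers)
    plots <- sample_survey_plots(cover, strata, wc$n_plots, wc$survey_years,
                                 seed = substream_seed(wc$seed, "survey"))
    plot_features <- dplyr::inner_join(
      dplyr::select(plots, "plot_id", "pixel_id", "year", "stratum",
                    "n_points", "bare_points", "bare_fraction"),
      dplyr::select(features, -"row", -"col"),
      by = c("pixel_id", "year"))
    model <- train_bgi(plot_features, algorithms = config$algorithms,
                       seed = substream_seed(wc$seed, "model"))
    put("plots", plots, "plots.csv", "train")
    put("model", model)
    put("model_scores", model$scores, "model_scores.csv", "train")
    js <- list(chosen = model$chosen, selection = model$selection_log,
               n_train = model$n_train, n_holdout = model$n_holdout,
               feature_stats = model$stats)
    jsonlite::write_json(js, file.path(outdir, "model_summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
    note("train", "model_summary.json")
  })

  run_stage("predict", function() {
    if (!exists("model", envir = mem)) {
      stop("missing upstream model object: rerun stage 'train'")
    }
    features <- get_obj("features", "features.csv", "features")
    scores <- predict_series(get("model", envir = mem), features,
                             config$reference_year)
    put("scores", scores, "scores.csv", "predict")
  })

  run_stage("resilience", function() {
    scores <- get_obj("scores", "scores.csv", "predict")
    coarse <- aggregate_to_coarse(scores, "bg_score", wc$block)
    res <- assess_resilience(coarse, "bg_score",
                             final_years = config$final_years,
                             k = config$k_shocks, alpha = config$alpha,
                             min_effect = config$min_effect,
                             guard = config$guard, n_boot = config$n_boot)
    put("coarse", coarse, "coarse_scores.csv", "resilience")
    put("resilience", res)
    put("classes", res$classes, "classes.csv", "resilience")
    utils::write.csv(as.data.frame(res$shocks),
                     file.path(outdir, "shock_years.csv"), row.names = FALSE)
    note("resilience", "shock_years.csv")
    utils::write.csv(tidy(res), file.path(outdir, "resilience_summary.csv"),
                     row.names = FALSE)
    note("resilience", "resilience_summary.csv")
    jsonlite::write_json(
      list(verdict = res$verdict$verdict,
           shock_years = res$shocks$year,
           resistance = res$resistance_contrasts,
           recovery = res$recovery_contrasts,
           alpha = config$alpha, min_effect = config$min_effect),
      file.path(outdir, "verdict.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "columns")
    note("resilience", "verdict.json")
  })

  run_stage("trend", function() {
    truth <- get_obj("truth", "truth.csv", "simulate")
    rainfall <- get_obj("rainfall", "rainfall.csv", "simulate")
    coarse <- get_obj("coarse", "coarse_scores.csv", "resilience")
    totals <- rainfall_totals(rainfall, "calendar")
    rates <- pixelwise_rate(coarse, totals, "bg_score")
    covars <- truth |>
      dplyr::summarise(human = mean(.data$human),
                       livestock = mean(.data$livestock),
                       designation = .mode_level(.data$designation),
                       .by = "cell_id") |>
      dplyr::left_join(
        dplyr::summarise(totals, rainfall = mean(.data$rain_total),
                         .by = "cell_id"),
        by = "cell_id")
    trend_df <- dplyr::inner_join(rates, covars, by = "cell_id")
    fit <- fit_spatial_model(trend_df)
    calib <- calibration_check(fit)
    put("rates", rates, "trend_rates.csv", "trend")
    put("trend_fit", fit)
    utils::write.csv(tidy(fit), file.path(outdir, "trend_coefficients.csv"),
                     row.names = FALSE)
    note("trend", "trend_coefficients.csv")
    utils::write.csv(calib$histogram,
                     file.path(outdir, "calibration_histogram.csv"),
                     row.names = FALSE)
    note("trend", "calibration_histogram.csv")
  })

  art_tbl <- dplyr::bind_rows(arts)
  art_tbl$md5 <- unname(tools::md5sum(file.path(outdir, art_tbl$artifact)))
  jsonlite::write_json(art_tbl, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  structure(list(artifacts = art_tbl, outdir = outdir, stages = stages,
                 timings = unlist(timings),
                 results = as.list(mem)),
            class = "rw_manifest")
}

#' @export
print.rw_manifest <- function(x, ...) {
  cat(sprintf("<rw_manifest> %d artifact(s) in %s\n", nrow(x$artifacts),
              x$outdir))
  print(x$artifacts)
  invisible(x)
}
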