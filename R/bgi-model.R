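# Bare-ground-index regression protocol: holdout split, response transform,
# repeated random cross-validation over candidate algorithms, model selection,
# and prediction with reference-year scaling.

#' Fixed hyperparameter defaults for the candidate regressors
#'
#' The comparison protocol (holdout split, repeated cross-validation,
#' selection rule) is the reproducible object; hyperparameters are small fixed
#' defaults recorded here and logged in the fitted model.
#'
#' @param rf,svr,gbt Named lists overriding individual defaults.
#' @return A named list of per-algorithm settings.
#' @export
bgi_control <- function(rf = list(), svr = list(), gbt = list()) {
  list(
    rf = utils::modifyList(list(num_trees = 500, min_node_size = 5), rf),
    svr = utils::modifyList(list(nu = 0.5, cost = 1), svr),
    gbt = utils::modifyList(
      list(nrounds = 200, eta = 0.1, max_depth = 3, subsample = 0.8), gbt)
  )
}

#' Split survey plots into training and holdout partitions
#'
#' @param plots A data frame of survey plots (one row per plot).
#' @param fraction Holdout fraction in (0, 1); default 0.25.
#' @param seed Integer seed making the split reproducible.
#' @return A list with tibbles `train` and `holdout`; disjoint and exhaustive.
#' @examples
#' p <- tibble::tibble(plot_id = 1:256)
#' lengths(split_holdout(p, seed = 1))
#' @export
split_holdout <- function(plots, fraction = 0.25, seed) {
  if (fraction <= 0 || fraction >= 1) stop("`fraction` must lie in (0, 1)")
  n <- nrow(plots)
  if (n < 8) stop("need at least 8 plots to split")
  set.seed(seed)
  n_hold <- round(n * fraction)
  hold <- sample.int(n, n_hold)
  list(train = tibble::as_tibble(plots[-hold, ]),
       holdout = tibble::as_tibble(plots[hold, ]))
}

#' Response transform for bare-ground percent
#'
#' Bare-ground percentages are right-skewed towards zero; the model is fitted
#' on `log(x + 1)` and predictions are back-transformed with `exp(y) - 1`.
#'
#' @param x Bare ground percent (0-100), non-negative.
#' @param y Model-scale response.
#' @return Transformed (resp. back-transformed) numeric vector.
#' @export
transform_response <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("bare-ground percent must be non-negative")
  log1p(x)
}

#' @rdname transform_response
#' @export
back_transform_response <- function(y) expm1(y)

# --- algorithm wrappers ------------------------------------------------------

fit_algorithm <- function(algorithm, x, y, control = bgi_control(), seed = 1) {
  x <- as.matrix(x)
  # a custom regressor is a function(x, y) returning a prediction function;
  # it runs through the identical protocol as the built-in algorithms
  if (is.function(algorithm)) {
    pred_fun <- algorithm(x, y)
    return(structure(list(algorithm = "custom", fit = pred_fun,
                          predictors = colnames(x)),
                     class = "rw_regressor"))
  }
  fit <- switch(algorithm,
    rf = ranger::ranger(
      x = x, y = y, num.trees = control$rf$num_trees,
      min.node.size = control$rf$min_node_size, seed = seed, num.threads = 1),
    svr = e1071::svm(
      x = x, y = y, type = "nu-regression", kernel = "radial",
      nu = control$svr$nu, cost = control$svr$cost, scale = FALSE),
    gbt = {
      set.seed(seed)
      xgboost::xgb.train(
        params = list(eta = control$gbt$eta, max_depth = control$gbt$max_depth,
                      subsample = control$gbt$subsample,
                      objective = "reg:squarederror", nthread = 1),
        data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
        nrounds = control$gbt$nrounds, verbose = 0)
    },
    stop(sprintf("unknown algorithm '%s'", algorithm))
  )
  structure(list(algorithm = algorithm, fit = fit, predictors = colnames(x)),
            class = "rw_regressor")
}

predict_regressor <- function(object, x) {
  x <- as.matrix(x[, object$predictors, drop = FALSE])
  if (object$algorithm == "custom") return(as.numeric(object$fit(x)))
  switch(object$algorithm,
    rf = stats::predict(object$fit, data = x, num.threads = 1)$predictions,
    svr = as.numeric(stats::predict(object$fit, newdata = x)),
    gbt = stats::predict(object$fit, xgboost::xgb.DMatrix(x, nthread = 1))
  )
}

.rmse <- function(obs, pred) sqrt(mean((obs - pred)^2))
.r2 <- function(obs, pred) {
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((obs - pred)^2) / ss_tot
}

#' Repeated random cross-validation of one algorithm
#'
#' Runs `repeats` fresh random splits of the training partition into an inner
#' training subset (`inner_fraction`) and a validation subset, fitting the
#' algorithm on the former and scoring RMSE and R-squared (coefficient of
#' determination, computed on the transformed response scale) on the latter.
#' A validation subset with constant response yields an undefined R-squared
#' for that repeat, recorded as `NA` and excluded from summary means.
#'
#' @param data Training partition with standardized predictors and the
#'   transformed response.
#' @param algorithm One of `"rf"`, `"svr"`, `"gbt"`.
#' @param response Response column (default `"bg_log"`).
#' @param predictors Predictor columns.
#' @param repeats Number of repeats (default 10).
#' @param inner_fraction Inner training fraction (default 0.75).
#' @param seed Integer seed; identical seeds reproduce identical score vectors.
#' @param control Hyperparameters from [bgi_control()].
#' @return A tibble with one row per repeat: `algorithm`, `repeat_id`, `rmse`,
#'   `r2`.
#' @export
repeated_cv <- function(data, algorithm, response = "bg_log",
                        predictors = feature_predictors(data),
                        repeats = 10, inner_fraction = 0.75, seed = 1,
                        control = bgi_control()) {
  if (inner_fraction <= 0 || inner_fraction >= 1) {
    stop("`inner_fraction` must lie in (0, 1)")
  }
  n <- nrow(data)
  purrr::map_dfr(seq_len(repeats), function(r) {
    rep_seed <- seed + 7919L * r
    set.seed(rep_seed)
    idx <- sample.int(n, round(n * inner_fraction))
    fit <- fit_algorithm(algorithm, data[idx, predictors],
                         data[[response]][idx], control, seed = rep_seed)
    val <- data[-idx, , drop = FALSE]
    pred <- predict_regressor(fit, val)
    r2 <- .r2(val[[response]], pred)
    if (is.na(r2)) {
      message(sprintf("repeat %d: constant validation response, R2 undefined", r))
    }
    tibble::tibble(
      algorithm = if (is.function(algorithm)) "custom" else algorithm,
      repeat_id = r, rmse = .rmse(val[[response]], pred), r2 = r2)
  })
}

# Mean/sd summary of per-repeat scores.
cv_summarise <- function(cv) {
  dplyr::summarise(cv,
    rmse_mean = mean(.data$rmse), rmse_sd = stats::sd(.data$rmse),
    r2_mean = mean(.data$r2, na.rm = TRUE),
    r2_sd = stats::sd(.data$r2, na.rm = TRUE),
    .by = "algorithm")
}

#' Select the final algorithm from cross-validation and holdout scores
#'
#' Selection rule: best (lowest) holdout RMSE; ties broken by higher holdout
#' R-squared, then by lower cross-validation mean RMSE.
#'
#' @param scores A tibble with columns `algorithm`, `holdout_rmse`,
#'   `holdout_r2`, `rmse_mean`.
#' @return The chosen algorithm name (length-1 character).
#' @export
select_model <- function(scores) {
  if (nrow(scores) == 0) stop("no candidate algorithms to select from")
  ord <- order(scores$holdout_rmse, -scores$holdout_r2, scores$rmse_mean)
  scores$algorithm[ord[1]]
}

#' Train and select the bare-ground-index model
#'
#' Implements the full calibration protocol: split the plots 75/25 into
#' training and holdout partitions; standardize predictors with statistics
#' from the training partition only; fit each candidate algorithm under
#' repeated random cross-validation inside the training partition; evaluate
#' each candidate (fitted on the whole training partition) once against the
#' previously untouched holdout; select by the [select_model()] rule; and
#' refit the chosen algorithm on all plots for prediction.
#'
#' @param plot_features Survey plots joined with their predictor features;
#'   must contain `bare_fraction` (or `bare_points` and `n_points`) plus the
#'   predictor columns.
#' @param predictors Predictor columns (default: everything that is not a
#'   plot/response bookkeeping column).
#' @param algorithms Candidate algorithms.
#' @param holdout_fraction,repeats,inner_fraction Protocol settings.
#' @param seed Integer seed controlling the split, the CV repeats and any
#'   algorithm randomness.
#' @param control Hyperparameters from [bgi_control()].
#' @return An object of class `rw_bgi_model` with the chosen algorithm, the
#'   final fit, the standardization statistics, per-repeat CV scores, holdout
#'   scores and a selection log. Methods: [tidy.rw_bgi_model()],
#'   [glance.rw_bgi_model()], `print()`.
#' @export
train_bgi <- function(plot_features,
                      predictors = NULL,
                      algorithms = c("rf", "svr", "gbt"),
                      holdout_fraction = 0.25, repeats = 10,
                      inner_fraction = 0.75, seed = 1,
                      control = bgi_control()) {
  df <- tibble::as_tibble(plot_features)
  if (!"bare_fraction" %in% names(df)) {
    if (!all(c("bare_points", "n_points") %in% names(df))) {
      stop("plots must carry `bare_fraction` or `bare_points` + `n_points`")
    }
    df$bare_fraction <- df$bare_points / df$n_points
  }
  df$bg_log <- transform_response(100 * df$bare_fraction)
  if (is.null(predictors)) predictors <- feature_predictors(df)
  # algorithms: built-in names, or a *named* list that may mix names and
  # custom function(x, y) regressors
  algs <- if (is.character(algorithms)) {
    stats::setNames(as.list(algorithms), algorithms)
  } else {
    if (is.null(names(algorithms)) || any(names(algorithms) == "")) {
      stop("a list of algorithms must be named")
    }
    algorithms
  }
  parts <- split_holdout(df, holdout_fraction, seed)
  stats <- feature_stats(parts$train, predictors)
  train_s <- standardize_features(parts$train, stats)
  hold_s <- standardize_features(parts$holdout, stats)
  cv <- purrr::map_dfr(names(algs), function(nm) {
    out <- repeated_cv(train_s, algs[[nm]], predictors = predictors,
                       repeats = repeats, inner_fraction = inner_fraction,
                       seed = seed, control = control)
    out$algorithm <- nm
    out
  })
  holdout <- purrr::map_dfr(names(algs), function(nm) {
    fit <- fit_algorithm(algs[[nm]], train_s[, predictors], train_s$bg_log,
                         control, seed = seed)
    pred <- predict_regressor(fit, hold_s)
    tibble::tibble(algorithm = nm,
                   holdout_rmse = .rmse(hold_s$bg_log, pred),
                   holdout_r2 = .r2(hold_s$bg_log, pred),
                   holdout_r2_pearson = stats::cor(hold_s$bg_log, pred)^2)
  })
  scores <- dplyr::left_join(cv_summarise(cv), holdout, by = "algorithm")
  chosen <- select_model(scores)
  all_s <- standardize_features(df, stats)
  final <- fit_algorithm(algs[[chosen]], all_s[, predictors], all_s$bg_log,
                         control, seed = seed)
  structure(list(
    chosen = chosen, fit = final, stats = stats, predictors = predictors,
    cv = cv, scores = scores, seed = seed, control = control,
    n_train = nrow(parts$train), n_holdout = nrow(parts$holdout),
    selection_log = sprintf(
      "selected %s by holdout RMSE (%s)", chosen,
      paste(sprintf("%s=%.3f", scores$algorithm, scores$holdout_rmse),
            collapse = ", "))
  ), class = "rw_bgi_model")
}

#' @export
print.rw_bgi_model <- function(x, ...) {
  cat("<rw_bgi_model>\n")
  cat(sprintf("  %d train / %d holdout plots, %d predictors\n",
              x$n_train, x$n_holdout, length(x$predictors)))
  cat(" ", x$selection_log, "\n")
  print(x$scores)
  invisible(x)
}

#' Broom-style accessors for a bare-ground-index model
#'
#' `tidy()` returns the per-algorithm comparison table (cross-validation mean
#' and sd of RMSE and R-squared plus holdout scores); `glance()` returns a
#' one-row summary of the chosen model.
#'
#' @param x An `rw_bgi_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.rw_bgi_model <- function(x, ...) x$scores

#' @rdname tidy.rw_bgi_model
#' @export
glance.rw_bgi_model <- function(x, ...) {
  sc <- x$scores[x$scores$algorithm == x$chosen, ]
  tibble::tibble(algorithm = x$chosen, holdout_rmse = sc$holdout_rmse,
                 holdout_r2 = sc$holdout_r2, cv_rmse_mean = sc$rmse_mean,
                 cv_r2_mean = sc$r2_mean, n_train = x$n_train,
                 n_holdout = x$n_holdout)
}

#' Predict the bare-ground series and derive its score layers
#'
#' Applies the final model to every pixel-year: predictions are
#' back-transformed from the log scale (`exp(y) - 1`, percent bare ground),
#' z-scored against the spatial mean and standard deviation of the reference
#' year's map (so the reference year has mean 0, sd 1 by construction), and
#' min-max normalized to `[0, 1]` globally across all pixel-years (per-year
#' normalization would destroy inter-annual trends). The three layers are
#' monotone transforms of one another.
#'
#' @param model An `rw_bgi_model`.
#' @param features Unstandardized feature table for all pixel-years.
#' @param reference_year Scaling reference year (default 2016).
#' @return A tibble `pixel_id`, `row`, `col`, `year`, `bg_raw`, `bg_scaled`,
#'   `bg_score`.
#' @export
predict_series <- function(model, features, reference_year = 2016) {
  stopifnot(inherits(model, "rw_bgi_model"))
  fs <- standardize_features(features, model$stats)
  pred <- predict_regressor(model$fit, fs[, model$predictors, drop = FALSE])
  raw <- back_transform_response(pred)
  ref <- raw[features$year == reference_year]
  if (length(ref) == 0) {
    stop(sprintf("reference year %d absent from features", reference_year))
  }
  mu <- mean(ref); sigma <- stats::sd(ref)
  if (is.na(sigma) || sigma == 0) stop("reference-year predictions are constant")
  scaled <- (raw - mu) / sigma
  rng <- range(scaled)
  score <- (scaled - rng[1]) / diff(rng)
  keep <- intersect(c("pixel_id", "row", "col", "year"), names(features))
  dplyr::bind_cols(features[, keep],
                   tibble::tibble(bg_raw = raw, bg_scaled = scaled,
                                  bg_score = score))
}
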