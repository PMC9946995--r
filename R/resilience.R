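# Resistance vs recovery analysis: coarse aggregation, degradation tertiles,
# shock-year detection, per-class resistance/recovery statistics, two-way
# ANOVA comparisons and the mechanism verdict.

.safe_median <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) NA_real_ else stats::median(x)
}

#' Aggregate a fine-grid layer to coarse cells
#'
#' Aggregates non-overlapping `block` x `block` blocks of fine pixels
#' (anchored at the grid origin) to one coarse cell each, using the median so
#' extreme fine pixels do not dominate; 7 x 7 blocks of 30 m pixels give a
#' nominal 210 m cell. Masked (`NA`) fine pixels are excluded; a fully masked
#' block yields a masked coarse cell.
#'
#' @param data Tibble with `row`, `col`, optionally `year`, and the value
#'   column.
#' @param value Name of the value column (tidy-select, default `bg_score`).
#' @param block Fine pixels per coarse-cell side.
#' @param statistic `"median"` (default) or `"mean"`.
#' @return A tibble `cell_id`, `row`, `col` (coarse coordinates), optionally
#'   `year`, and the aggregated value column (same name as the input).
#' @export
aggregate_to_coarse <- function(data, value = "bg_score", block = 7,
                                statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  stopifnot(block >= 1)
  agg <- if (statistic == "median") .safe_median else function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) NA_real_ else mean(x)
  }
  nr_coarse <- max((data$row - 1L) %/% block + 1L)
  df <- dplyr::mutate(data,
    crow = (.data$row - 1L) %/% block + 1L,
    ccol = (.data$col - 1L) %/% block + 1L)
  keys <- c("crow", "ccol", intersect("year", names(data)))
  out <- dplyr::summarise(df, value = agg(.data[[value]]), .by = dplyr::all_of(keys))
  out <- dplyr::mutate(out, cell_id = (.data$ccol - 1L) * nr_coarse + .data$crow)
  out <- dplyr::rename(out, row = "crow", col = "ccol")
  names(out)[names(out) == "value"] <- value
  dplyr::relocate(dplyr::arrange(out, .data$cell_id), "cell_id")
}

#' Min-max normalize a score column to the unit interval
#'
#' @param data A tibble.
#' @param value Name of the column to normalize.
#' @return `data` with the column rescaled to `[0, 1]` across all rows.
#' @export
normalize_scores <- function(data, value = "bg_score") {
  rng <- range(data[[value]], na.rm = TRUE)
  if (diff(rng) == 0) stop("cannot normalize a constant score column")
  data[[value]] <- (data[[value]] - rng[1]) / diff(rng)
  data
}

#' Classify cells into degradation tertiles
#'
#' Ranks cells by their median score over the final years of the series and
#' splits them into three classes of (near-)equal size: `least`, `medium` and
#' `most` degraded. Ties are broken by cell id, so classification is
#' deterministic and invariant to both row order and any strictly monotone
#' transform of the score.
#'
#' @param data Coarse score tibble (`cell_id`, `year`, value column).
#' @param final_years Years defining the basis statistic (default 2018-2020).
#' @param value Score column name.
#' @return A tibble `cell_id`, `basis`, `class` (factor
#'   `least < medium < most`).
#' @export
classify_tertiles <- function(data, final_years = c(2018, 2019, 2020),
                              value = "bg_score") {
  if (!all(final_years %in% data$year)) {
    stop("all `final_years` must be present in the series")
  }
  basis <- dplyr::filter(data, .data$year %in% final_years) |>
    dplyr::summarise(basis = .safe_median(.data[[value]]), .by = "cell_id") |>
    dplyr::arrange(.data$cell_id)
  n <- nrow(basis)
  if (n < 3) stop("need at least 3 cells to form tertiles")
  sizes <- rep(n %/% 3, 3)
  rem <- n %% 3
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1
  ord <- order(basis$basis, basis$cell_id)
  cls <- rep(c("least", "medium", "most"), times = sizes)
  basis$class <- factor(NA, levels = c("least", "medium", "most"))
  basis$class[ord] <- factor(cls, levels = c("least", "medium", "most"))
  basis
}

#' Detect shock years from the landscape median
#'
#' Computes the year-over-year change of the landscape-median score and takes
#' the `k` largest increases; each shock year is labelled by the later year of
#' the pair. In the study system these are drought years of widespread
#' bare-ground increase. A detected year whose change is not positive is kept
#' but flagged `weak`.
#'
#' @param data Coarse score tibble with `cell_id`, `year` and the value column.
#' @param k Number of shock years (default 4).
#' @param value Score column name.
#' @return An `rw_shock_set`: tibble `year`, `delta`, `weak` (year order),
#'   with the per-year landscape medians as attribute `"medians"`.
#' @export
detect_shock_years <- function(data, k = 4, value = "bg_score") {
  med <- dplyr::summarise(data, median = .safe_median(.data[[value]]),
                          .by = "year") |>
    dplyr::arrange(.data$year)
  if (k >= nrow(med) - 1) {
    stop("`k` must be smaller than the number of year-over-year steps")
  }
  delta <- diff(med$median)
  years <- med$year[-1]
  top <- order(delta, decreasing = TRUE)[seq_len(k)]
  d_top <- delta[top]
  out <- tibble::tibble(year = years[top], delta = d_top,
                        weak = d_top <= 0) |>
    dplyr::arrange(.data$year)
  structure(out, medians = med, class = c("rw_shock_set", class(out)))
}

#' @export
print.rw_shock_set <- function(x, ...) {
  cat(sprintf("<rw_shock_set> %d shock year(s): %s\n", nrow(x),
              paste(x$year, collapse = ", ")))
  NextMethod()
}

.join_classes <- function(records, classes) {
  out <- dplyr::inner_join(records,
                           dplyr::select(classes, "cell_id", "class"),
                           by = "cell_id")
  missing <- setdiff(levels(classes$class), unique(as.character(out$class)))
  if (length(missing) > 0) {
    stop(sprintf("class absent from records: %s", paste(missing, collapse = ", ")))
  }
  out
}

.class_summary <- function(records, value, n_boot, conf) {
  dplyr::summarise(records,
    median = .safe_median(.data[[value]]),
    ci_lo = boot_median_ci(.data[[value]], n_boot, conf)[["lo"]],
    ci_hi = boot_median_ci(.data[[value]], n_boot, conf)[["hi"]],
    n = sum(!is.na(.data[[value]])),
    .by = "class") |>
    dplyr::arrange(.data$class)
}

#' Per-class shock-year decline (resistance)
#'
#' For one shock year `s`, computes each cell's score change
#' `delta = score[s] - score[s - 1]` and summarises it by degradation class.
#' A larger increase means a lower resistance to the shock.
#'
#' @param data Coarse score tibble (`cell_id`, `year`, value column).
#' @param classes Tertile classification from [classify_tertiles()].
#' @param shock_year The shock year (the later year of the increase).
#' @param value Score column name.
#' @param n_boot Bootstrap resamples for the median CI (0 to skip).
#' @param conf CI level.
#' @return An `rw_class_stats` list: `records` (per-cell deltas with class),
#'   `summary` (per-class median with bootstrap CI and n), `shock_year`,
#'   `metric`.
#' @export
resistance_by_class <- function(data, classes, shock_year, value = "bg_score",
                                n_boot = 1000, conf = 0.95) {
  if (!all(c(shock_year - 1, shock_year) %in% data$year)) {
    stop(sprintf("years %d and %d must both be present", shock_year - 1, shock_year))
  }
  wide <- dplyr::filter(data, .data$year %in% c(shock_year - 1, shock_year)) |>
    dplyr::select("cell_id", "year", dplyr::all_of(value)) |>
    tidyr::pivot_wider(names_from = "year", values_from = dplyr::all_of(value),
                       names_prefix = "y")
  records <- tibble::tibble(
    cell_id = wide$cell_id,
    delta_shock = wide[[paste0("y", shock_year)]] -
      wide[[paste0("y", shock_year - 1)]]
  ) |> .join_classes(classes)
  structure(list(records = records,
                 summary = .class_summary(records, "delta_shock", n_boot, conf),
                 shock_year = shock_year, metric = "resistance"),
            class = "rw_class_stats")
}

#' Relative recovery: proportion of the shock-year decline regained
#'
#' With `delta_shock` the shock-year score increase and `delta_rec` the score
#' change in the following year, relative recovery is
#' `-delta_rec / delta_shock`: 1 means the recovery-year decrease exactly
#' offsets the shock-year increase (total recovery), 0 no recovery, negative
#' values continued decline, and values above 1 net improvement. Records with
#' `|delta_shock|` below `guard` are undefined (`NA`) to avoid ratio blow-up.
#'
#' @param delta_shock,delta_rec Numeric vectors of score changes.
#' @param guard Minimum absolute shock size (normalized units).
#' @return Numeric vector of relative recoveries.
#' @examples
#' relative_recovery(0.2, -0.2)  # total recovery: 1
#' relative_recovery(0.2, 0.1)   # continued decline: -0.5
#' @export
relative_recovery <- function(delta_shock, delta_rec, guard = 0.01) {
  out <- -delta_rec / delta_shock
  out[abs(delta_shock) < guard] <- NA_real_
  out
}

#' Per-class post-shock recovery
#'
#' For one shock year `s`, computes each cell's recovery in the following
#' year: `absolute` recovery is `-(score[s + 1] - score[s])` (units of score
#' regained), `relative` recovery is the proportion of the shock-year decline
#' regained (see [relative_recovery()]).
#'
#' @inheritParams resistance_by_class
#' @param mode `"absolute"` or `"relative"`.
#' @param guard Relative-recovery guard on `|delta_shock|`.
#' @return An `rw_class_stats` list as in [resistance_by_class()]; records
#'   carry `delta_shock`, `delta_rec`, `absolute_recovery` and
#'   `relative_recovery`.
#' @export
recovery_by_class <- function(data, classes, shock_year,
                              mode = c("absolute", "relative"),
                              value = "bg_score", guard = 0.01,
                              n_boot = 1000, conf = 0.95) {
  mode <- match.arg(mode)
  if (!(shock_year + 1) %in% data$year) {
    stop(sprintf("no recovery year: %d is the final year of the series",
                 shock_year))
  }
  yrs <- c(shock_year - 1, shock_year, shock_year + 1)
  if (!all(yrs %in% data$year)) stop("series must cover the shock and flanking years")
  wide <- dplyr::filter(data, .data$year %in% yrs) |>
    dplyr::select("cell_id", "year", dplyr::all_of(value)) |>
    tidyr::pivot_wider(names_from = "year", values_from = dplyr::all_of(value),
                       names_prefix = "y")
  ds <- wide[[paste0("y", shock_year)]] - wide[[paste0("y", shock_year - 1)]]
  dr <- wide[[paste0("y", shock_year + 1)]] - wide[[paste0("y", shock_year)]]
  records <- tibble::tibble(
    cell_id = wide$cell_id, delta_shock = ds, delta_rec = dr,
    absolute_recovery = -dr,
    relative_recovery = relative_recovery(ds, dr, guard)
  ) |> .join_classes(classes)
  vcol <- paste0(mode, "_recovery")
  structure(list(records = records,
                 summary = .class_summary(records, vcol, n_boot, conf),
                 shock_year = shock_year, metric = paste0(mode, "_recovery")),
            class = "rw_class_stats")
}

#' @export
print.rw_class_stats <- function(x, ...) {
  cat(sprintf("<rw_class_stats> %s, shock year %d\n", x$metric, x$shock_year))
  print(x$summary)
  invisible(x)
}

#' Two-way ANOVA comparison of classes across years
#'
#' Fits `value ~ class * year` (both as factors), estimates marginal means per
#' class within year, and runs Tukey-adjusted pairwise contrasts between
#' classes within each year. Because sample sizes are large, p-values are
#' reported alongside the contrast estimates (effect sizes) rather than alone.
#'
#' @param data Tibble with the value, class and year columns.
#' @param value,class,year Column names.
#' @param alpha Significance level for the `"n.s."` flag.
#' @return An `rw_class_anova` list: `anova` (term table with F and p),
#'   `emmeans` (marginal means per class and year), `contrasts` (per-year
#'   Tukey pairwise contrasts with a significance flag), `degenerate`.
#' @export
compare_classes <- function(data, value = "value", class = "class",
                            year = "year", alpha = 0.05) {
  df <- tibble::tibble(
    value = data[[value]],
    class = factor(data[[class]]),
    year = factor(data[[year]])
  )
  df <- df[stats::complete.cases(df), ]
  if (nlevels(droplevels(df$class)) < 2 || nlevels(droplevels(df$year)) < 2) {
    stop("need at least 2 classes and 2 years")
  }
  cells <- table(df$class, df$year)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty design cell: class %s, year %s",
                 rownames(cells)[empty[1]], colnames(cells)[empty[2]]))
  }
  if (stats::var(df$value) == 0) {
    return(structure(list(
      anova = tibble::tibble(), emmeans = tibble::tibble(),
      contrasts = tibble::tibble(), degenerate = TRUE, alpha = alpha),
      class = "rw_class_anova"))
  }
  fit <- stats::aov(value ~ class * year, data = df)
  at <- as.data.frame(summary(fit)[[1]])
  anova_tbl <- tibble::tibble(
    term = trimws(rownames(at)), df = at$Df, sumsq = at$`Sum Sq`,
    statistic = at$`F value`, p.value = at$`Pr(>F)`)
  emm <- emmeans::emmeans(fit, ~ class | year, data = df)
  emm_tbl <- tibble::as_tibble(as.data.frame(emm))
  ctr <- tibble::as_tibble(as.data.frame(
    emmeans::contrast(emm, method = "pairwise", adjust = "tukey")))
  ctr$flag <- ifelse(ctr$p.value < alpha, "*", "n.s.")
  structure(list(anova = anova_tbl, emmeans = emm_tbl, contrasts = ctr,
                 degenerate = FALSE, alpha = alpha),
            class = "rw_class_anova")
}

#' @export
print.rw_class_anova <- function(x, ...) {
  cat("<rw_class_anova>\n")
  if (x$degenerate) {
    cat("  degenerate: zero between-group variance\n")
  } else {
    print(x$anova)
  }
  invisible(x)
}

#' @export
tidy.rw_class_anova <- function(x, ...) x$anova

# Extract the (most - least) contrast per year from an rw_class_anova.
.most_vs_least <- function(cmp) {
  ctr <- cmp$contrasts
  sel <- ctr$contrast %in% c("most - least", "least - most")
  ctr <- ctr[sel, ]
  est <- ifelse(ctr$contrast == "least - most", -ctr$estimate, ctr$estimate)
  tibble::tibble(year = as.integer(as.character(ctr$year)),
                 estimate = est, p.value = ctr$p.value)
}

#' Mechanism verdict: loss of resistance vs loss of recovery
#'
#' Classifies the degradation mechanism from per-shock-year class contrasts.
#' If degradation is driven by a loss of resistance, the eventually
#' most-degraded class shows a significantly larger shock-year increase in a
#' majority of shock years while its absolute recovery is not significantly
#' smaller in a majority of recovery years; a loss of recovery shows the
#' mirror pattern (indistinguishable shock response, significantly smaller
#' recovery). Both patterns give `"mixed"`, neither `"indeterminate"`.
#' "Significantly" means Tukey-adjusted `p < alpha` *and* a most-vs-least
#' median difference exceeding `min_effect` - at these sample sizes p-values
#' alone are nearly always small, so an effect-size floor is applied.
#'
#' A recovery year in which essentially no recovery occurred anywhere on the
#' landscape (dry relief year) carries no information about recovery
#' capacity: when `recovery` has a `landscape_recovery` column, the recovery
#' majority is taken over the years whose landscape-median absolute recovery
#' exceeds `min_effect`, mirroring the observation that class differences in
#' recovery only express themselves in years with rain to recover on. If no
#' recovery year is informative, the recovery evidence is treated as absent.
#'
#' @param resistance Tibble with one row per shock year: `year`, `med_diff`
#'   (most-class median minus least-class median of the shock-year change)
#'   and `p_value`.
#' @param recovery Same layout for absolute recovery; optionally a
#'   `landscape_recovery` column (landscape-median absolute recovery).
#' @param alpha Significance level.
#' @param min_effect Minimum absolute median difference (normalized score
#'   units).
#' @return An `rw_verdict` list: `verdict` (one of `loss_of_resistance`,
#'   `loss_of_recovery`, `mixed`, `indeterminate`), per-year flag tables and
#'   the decision parameters.
#' @export
mechanism_verdict <- function(resistance, recovery, alpha = 0.05,
                              min_effect = 0.01) {
  if (nrow(resistance) < 2) stop("need at least 2 analyzed shock years")
  res_flag <- resistance$p_value < alpha & resistance$med_diff > min_effect
  rec_flag <- recovery$p_value < alpha & recovery$med_diff < -min_effect
  informative <- if ("landscape_recovery" %in% names(recovery)) {
    recovery$landscape_recovery > min_effect
  } else {
    rep(TRUE, nrow(recovery))
  }
  res_major <- mean(res_flag) > 0.5
  rec_major <- any(informative) && mean(rec_flag[informative]) > 0.5
  verdict <- if (res_major && rec_major) "mixed"
  else if (res_major) "loss_of_resistance"
  else if (rec_major) "loss_of_recovery"
  else "indeterminate"
  structure(list(
    verdict = verdict,
    resistance = dplyr::mutate(resistance, lower_resistance = res_flag),
    recovery = dplyr::mutate(recovery, lower_recovery = rec_flag,
                             informative = informative),
    alpha = alpha, min_effect = min_effect
  ), class = "rw_verdict")
}

#' @export
print.rw_verdict <- function(x, ...) {
  cat(sprintf("<rw_verdict> %s\n", x$verdict))
  cat(sprintf("  shock years with larger decline in most-degraded class: %d/%d\n",
              sum(x$resistance$lower_resistance), nrow(x$resistance)))
  cat(sprintf("  recovery years with smaller recovery in most-degraded class: %d/%d\n",
              sum(x$recovery$lower_recovery), nrow(x$recovery)))
  invisible(x)
}

#' Run the full resistance/recovery analysis on a score series
#'
#' Orchestrates the resilience stage on a coarse, normalized score series:
#' classify degradation tertiles from the final years, detect shock years from
#' the landscape median, compute per-class shock-year declines and post-shock
#' recoveries, compare classes with two-way ANOVAs and Tukey contrasts, and
#' derive the mechanism verdict.
#'
#' @param data Coarse normalized score tibble (`cell_id`, `year`, value
#'   column).
#' @param value Score column name.
#' @param final_years Years defining the tertile basis (default: last three
#'   years of the series).
#' @param k Number of shock years.
#' @param alpha,min_effect Verdict decision parameters, see
#'   [mechanism_verdict()].
#' @param guard Relative-recovery guard.
#' @param n_boot Bootstrap resamples for summary CIs.
#' @param classes Optional externally supplied classification (a
#'   `cell_id`/`class` tibble as returned by [classify_tertiles()]), e.g. for
#'   sensitivity analyses; by default the tertiles are computed from
#'   `final_years`.
#' @return An `rw_resilience` list: `classes`, `shocks`, per-shock-year
#'   `resistance` and `recovery` statistics, the two `rw_class_anova`
#'   comparisons, the per-year most-vs-least `contrasts`, and the `verdict`.
#'   Methods: `tidy()` (class-year summaries), `glance()` (verdict row).
#' @export
assess_resilience <- function(data, value = "bg_score", final_years = NULL,
                              k = 4, alpha = 0.05, min_effect = 0.01,
                              guard = 0.01, n_boot = 200, classes = NULL) {
  years <- sort(unique(data$year))
  if (is.null(final_years)) final_years <- utils::tail(years, 3)
  if (is.null(classes)) classes <- classify_tertiles(data, final_years, value)
  shocks <- detect_shock_years(data, k, value)
  res_stats <- purrr::map(shocks$year, function(s) {
    resistance_by_class(data, classes, s, value, n_boot = n_boot)
  })
  rec_years <- shocks$year[(shocks$year + 1) %in% years]
  if (length(rec_years) < nrow(shocks)) {
    message(sprintf("skipping recovery for shock year(s) without a following year: %s",
                    paste(setdiff(shocks$year, rec_years), collapse = ", ")))
  }
  rec_stats <- purrr::map(rec_years, function(s) {
    recovery_by_class(data, classes, s, mode = "absolute", value = value,
                      guard = guard, n_boot = n_boot)
  })
  res_records <- purrr::map_dfr(res_stats, function(x) {
    dplyr::mutate(x$records, year = x$shock_year)
  })
  rec_records <- purrr::map_dfr(rec_stats, function(x) {
    dplyr::mutate(x$records, year = x$shock_year)
  })
  cmp_res <- compare_classes(res_records, value = "delta_shock", alpha = alpha)
  cmp_rec <- compare_classes(rec_records, value = "absolute_recovery",
                             alpha = alpha)
  med_diff <- function(records, col) {
    dplyr::summarise(records, med = .safe_median(.data[[col]]),
                     .by = c("year", "class")) |>
      tidyr::pivot_wider(names_from = "class", values_from = "med") |>
      dplyr::mutate(med_diff = .data$most - .data$least) |>
      dplyr::select("year", "med_diff")
  }
  res_tbl <- dplyr::left_join(med_diff(res_records, "delta_shock"),
                              .most_vs_least(cmp_res), by = "year") |>
    dplyr::rename(p_value = "p.value")
  rec_tbl <- dplyr::left_join(med_diff(rec_records, "absolute_recovery"),
                              .most_vs_least(cmp_rec), by = "year") |>
    dplyr::rename(p_value = "p.value") |>
    dplyr::left_join(
      dplyr::summarise(rec_records,
                       landscape_recovery = .safe_median(.data$absolute_recovery),
                       .by = "year"),
      by = "year")
  verdict <- mechanism_verdict(res_tbl, rec_tbl, alpha, min_effect)
  structure(list(
    classes = classes, shocks = shocks,
    resistance = res_stats, recovery = rec_stats,
    anova_resistance = cmp_res, anova_recovery = cmp_rec,
    resistance_contrasts = res_tbl, recovery_contrasts = rec_tbl,
    verdict = verdict
  ), class = "rw_resilience")
}

#' @export
print.rw_resilience <- function(x, ...) {
  cat("<rw_resilience>\n")
  cat(sprintf("  shock years: %s\n", paste(x$shocks$year, collapse = ", ")))
  print(x$verdict)
  invisible(x)
}

#' Broom-style accessors for a resilience analysis
#'
#' `tidy()` returns the per-class, per-shock-year summaries (median, bootstrap
#' CI and n for the shock-year decline and the absolute recovery); `glance()`
#' returns a one-row summary with the verdict.
#'
#' @param x An `rw_resilience`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.rw_resilience <- function(x, ...) {
  dplyr::bind_rows(
    purrr::map_dfr(x$resistance, function(s) {
      dplyr::mutate(s$summary, metric = s$metric, year = s$shock_year)
    }),
    purrr::map_dfr(x$recovery, function(s) {
      dplyr::mutate(s$summary, metric = s$metric, year = s$shock_year)
    })
  ) |> dplyr::relocate("metric", "year")
}

#' @rdname tidy.rw_resilience
#' @export
glance.rw_resilience <- function(x, ...) {
  tibble::tibble(
    verdict = x$verdict$verdict,
    n_shock_years = nrow(x$shocks),
    n_resistance_hits = sum(x$verdict$resistance$lower_resistance),
    n_recovery_hits = sum(x$verdict$recovery$lower_recovery),
    alpha = x$verdict$alpha, min_effect = x$verdict$min_effect
  )
}
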