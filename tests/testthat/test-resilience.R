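grid_df <- function(nr, nc, values, year = NULL) {
  df <- tibble::tibble(
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr),
    bg_score = values
  )
  if (!is.null(year)) df$year <- year
  df
}

test_that("coarse aggregation takes robust block medians", {
  # constant block
  df <- grid_df(7, 7, rep(0.4, 49))
  expect_equal(aggregate_to_coarse(df, block = 7)$bg_score, 0.4)
  # 48 zeros and a single one: median stays 0
  df2 <- grid_df(7, 7, c(rep(0, 48), 1))
  expect_equal(aggregate_to_coarse(df2, block = 7)$bg_score, 0)
  # fully masked block -> masked cell
  df3 <- grid_df(7, 7, NA_real_)
  expect_true(is.na(aggregate_to_coarse(df3, block = 7)$bg_score))
})

test_that("coarse aggregation equals a brute-force sort-and-middle oracle", {
  set.seed(10)
  df <- grid_df(21, 21, stats::runif(441))
  got <- aggregate_to_coarse(df, block = 7)
  for (i in seq_len(nrow(got))) {
    sel <- df$bg_score[(df$row - 1) %/% 7 + 1 == got$row[i] &
                         (df$col - 1) %/% 7 + 1 == got$col[i]]
    s <- sort(sel)
    oracle <- (s[25] + s[25]) / 2  # odd count: middle element
    expect_equal(got$bg_score[i], oracle)
  }
})

test_that("tertile classes are balanced, rank-based and order-stable", {
  df <- tibble::tibble(cell_id = 1:9, year = 2018, bg_score = c(1:9) / 10)
  cls <- classify_tertiles(df, final_years = 2018)
  expect_equal(as.character(cls$class),
               rep(c("least", "medium", "most"), each = 3))
  # all-equal basis still balances via the documented tie-break
  df2 <- dplyr::mutate(df, bg_score = 0.5)
  cls2 <- classify_tertiles(df2, final_years = 2018)
  expect_equal(unname(table(cls2$class)), array(c(3L, 3L, 3L)),
               ignore_attr = TRUE)
  # reversed presentation order yields identical labels
  cls3 <- classify_tertiles(df[9:1, ], final_years = 2018)
  expect_equal(cls3, cls)
  expect_error(classify_tertiles(df[1:2, ], final_years = 2018), "at least 3")
})

test_that("tertile classes are invariant to strictly monotone transforms", {
  set.seed(4)
  df <- tidyr::expand_grid(cell_id = 1:30, year = 2018:2020) |>
    dplyr::mutate(bg_score = stats::runif(dplyr::n()))
  base <- classify_tertiles(df)
  for (f in list(function(x) exp(x), function(x) x^3 + 2 * x,
                 function(x) -1 / (1 + x))) {
    tr <- classify_tertiles(dplyr::mutate(df, bg_score = f(bg_score)))
    expect_equal(tr$class, base$class)
  }
})

test_that("shock years are the largest landscape-median increases", {
  df <- tidyr::expand_grid(cell_id = 1:5, year = 2000:2003) |>
    dplyr::mutate(bg_score = c(0.2, 0.5, 0.4, 0.6)[match(year, 2000:2003)])
  s <- detect_shock_years(df, k = 1)
  expect_equal(s$year, 2001)
  expect_equal(s$delta, 0.3)
  expect_false(s$weak)
  # monotone decreasing series: least-negative step returned but flagged weak
  df2 <- dplyr::mutate(df, bg_score = c(0.9, 0.7, 0.6, 0.3)[match(year, 2000:2003)])
  s2 <- detect_shock_years(df2, k = 1)
  expect_equal(s2$year, 2002)
  expect_true(s2$weak)
  expect_error(detect_shock_years(df, k = 3), "smaller")
})

test_that("relative recovery reproduces the caption identities exactly", {
  expect_equal(relative_recovery(0.2, -0.2), 1)    # total recovery
  expect_equal(relative_recovery(0.2, 0), 0)       # no recovery
  expect_equal(relative_recovery(0.2, 0.1), -0.5)  # continued decline
  expect_equal(relative_recovery(0.2, -0.3), 1.5)  # net improvement
  expect_true(is.na(relative_recovery(0.005, -0.2)))  # guarded ratio
})

make_panel <- function(scores_by_year, n_cells = 9) {
  tidyr::expand_grid(cell_id = seq_len(n_cells),
                     year = as.integer(names(scores_by_year))) |>
    dplyr::mutate(bg_score = unname(scores_by_year[as.character(year)]))
}

test_that("identical series in all pixels give identical class medians", {
  sc <- c(`2009` = 0.2, `2010` = 0.5, `2011` = 0.3)
  df <- make_panel(sc)
  cls <- tibble::tibble(cell_id = 1:9,
                        class = factor(rep(c("least", "medium", "most"), 3),
                                       levels = c("least", "medium", "most")))
  res <- resistance_by_class(df, cls, 2010, n_boot = 0)
  expect_equal(unique(res$summary$median), 0.3)
  rec <- recovery_by_class(df, cls, 2010, n_boot = 0)
  expect_equal(unique(rec$summary$median), 0.2)
  expect_error(recovery_by_class(df, cls, 2011, n_boot = 0), "final year")
})

test_that("a class absent from the records raises an error", {
  sc <- c(`2009` = 0.2, `2010` = 0.5)
  df <- make_panel(sc, 4)
  cls <- tibble::tibble(cell_id = 1:4,
                        class = factor("most", levels = c("least", "medium", "most")))
  expect_error(resistance_by_class(df, cls, 2010, n_boot = 0), "least")
})

test_that("the two-way ANOVA matches a hand-rolled sum-of-squares oracle", {
  set.seed(8)
  n <- 50
  df <- tidyr::expand_grid(class = c("least", "most"), year = c(2005, 2010),
                           rep = seq_len(n)) |>
    dplyr::mutate(value = stats::rnorm(dplyr::n(), sd = 0.1) +
                    ifelse(class == "most", 1, 0))
  cmp <- compare_classes(df)
  # balanced design: classical sequential SS equal one-at-a-time sums
  mu <- mean(df$value)
  ss_class <- sum(tapply(df$value, df$class, function(v) length(v) * (mean(v) - mu)^2))
  cell_means <- tapply(df$value, list(df$class, df$year), mean)
  row_m <- rowMeans(cell_means); col_m <- colMeans(cell_means)
  ss_year <- sum(tapply(df$value, df$year, function(v) length(v) * (mean(v) - mu)^2))
  ss_int <- n * sum((cell_means - outer(row_m, rep(1, 2)) -
                       outer(rep(1, 2), col_m) + mu)^2)
  ss_res <- sum((df$value - ave(df$value, df$class, df$year))^2)
  f_class <- (ss_class / 1) / (ss_res / (nrow(df) - 4))
  got <- cmp$anova
  expect_equal(got$sumsq[got$term == "class"], ss_class, tolerance = 1e-8)
  expect_equal(got$sumsq[got$term == "year"], ss_year, tolerance = 1e-8)
  expect_equal(got$sumsq[got$term == "class:year"], ss_int, tolerance = 1e-8)
  expect_equal(got$statistic[got$term == "class"], f_class, tolerance = 1e-8)
  # marginal means recover the planted effect
  emm <- cmp$emmeans
  expect_equal(mean(emm$emmean[emm$class == "most"]) -
                 mean(emm$emmean[emm$class == "least"]), 1, tolerance = 0.05)
})

test_that("permuting class labels destroys the class effect", {
  set.seed(12)
  n <- 30
  df <- tidyr::expand_grid(class = c("least", "most"), year = c(2005, 2010),
                           rep = seq_len(n)) |>
    dplyr::mutate(value = stats::rnorm(dplyr::n(), sd = 0.1) +
                    ifelse(class == "most", 1, 0))
  ns <- 0
  for (i in 1:20) {
    perm <- dplyr::mutate(df, class = sample(class))
    p <- compare_classes(perm)$anova
    if (p$p.value[p$term == "class"] > 0.05) ns <- ns + 1
  }
  expect_gte(ns, 18)
})

test_that("degenerate and ill-formed comparisons are reported as such", {
  flat <- tidyr::expand_grid(class = c("a", "b"), year = 1:2, rep = 1:3) |>
    dplyr::mutate(value = 1)
  expect_true(compare_classes(flat)$degenerate)
  holey <- tidyr::expand_grid(class = c("a", "b"), year = 1:2, rep = 1:3) |>
    dplyr::mutate(value = stats::rnorm(12)) |>
    dplyr::filter(!(class == "b" & year == 2))
  expect_error(compare_classes(holey), "class b, year 2")
})

test_that("the mechanism verdict implements the decision logic", {
  sig_larger <- tibble::tibble(year = 1:4, med_diff = 0.05, p_value = 1e-6)
  flat <- tibble::tibble(year = 1:4, med_diff = 0.001, p_value = 0.5)
  sig_smaller <- tibble::tibble(year = 1:4, med_diff = -0.05, p_value = 1e-6)
  expect_equal(mechanism_verdict(sig_larger, flat)$verdict, "loss_of_resistance")
  expect_equal(mechanism_verdict(flat, sig_smaller)$verdict, "loss_of_recovery")
  expect_equal(mechanism_verdict(sig_larger, sig_smaller)$verdict, "mixed")
  expect_equal(mechanism_verdict(flat, flat)$verdict, "indeterminate")
  # significance without a meaningful effect size does not count
  tiny <- tibble::tibble(year = 1:4, med_diff = 0.002, p_value = 1e-6)
  expect_equal(mechanism_verdict(tiny, flat)$verdict, "indeterminate")
  expect_error(mechanism_verdict(sig_larger[1, ], flat), "at least 2")
})

test_that("scenario presets are discriminated end to end on one seed each", {
  for (preset in c("loss_of_resistance", "loss_of_recovery")) {
    w <- simulate_world(mid_config(seed = 31, preset = preset))
    res <- assess_resilience(truth_score_series(w), n_boot = 50)
    expect_equal(res$verdict$verdict, preset)
    expect_equal(res$shocks$year, w$config$shock_years)
    expect_s3_class(tidy(res), "tbl_df")
    expect_equal(glance(res)$verdict, preset)
  }
})

test_that("a shuffled class map yields an indeterminate verdict", {
  w <- simulate_world(mid_config(seed = 31))
  series <- truth_score_series(w)
  classes <- classify_tertiles(series)
  set.seed(99)
  shuffled <- dplyr::mutate(classes, class = sample(class))
  res <- assess_resilience(series, n_boot = 0, classes = shuffled)
  expect_equal(res$verdict$verdict, "indeterminate")
})

test_that("dry recovery years carry no vote in the recovery verdict", {
  flat <- tibble::tibble(year = 1:4, med_diff = 0.001, p_value = 0.5)
  rec <- tibble::tibble(
    year = 1:4,
    med_diff = c(-0.05, -0.001, -0.05, -0.002),
    p_value = c(1e-6, 0.9, 1e-6, 0.8),
    landscape_recovery = c(0.05, 0.002, 0.05, 0.003))
  # only the two wet years are informative, and both show lower recovery
  expect_equal(mechanism_verdict(flat, rec)$verdict, "loss_of_recovery")
  # without the landscape column all four years vote: 2/4 is not a majority
  expect_equal(mechanism_verdict(flat, rec[, 1:3])$verdict, "indeterminate")
  # no informative year at all: recovery evidence is absent
  dry <- dplyr::mutate(rec, landscape_recovery = 0.001)
  expect_equal(mechanism_verdict(flat, dry)$verdict, "indeterminate")
})
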