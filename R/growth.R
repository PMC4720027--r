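#' Join daily count records into per-feature time series
#'
#' Records from different imaging days are joined on (well, grid_row,
#' grid_col); days a feature was not imaged remain gaps (never interpolated).
#'
#' @param records Count-record tibble (`well`, `grid_row`, `grid_col`,
#'   `day`, `nucleus_count`), e.g. from [process_plate()] or
#'   [read_count_store()].
#' @return A nested tibble with one row per feature and list columns `days`
#'   (strictly increasing integers) and `counts`.
#' @export
join_timepoints <- function(records) {
  if (nrow(records) == 0L) {
    return(tibble(well = integer(), grid_row = integer(),
                  grid_col = integer(), days = list(), counts = list()))
  }
  records |>
    dplyr::arrange(.data$well, .data$grid_row, .data$grid_col, .data$day) |>
    dplyr::group_by(.data$well, .data$grid_row, .data$grid_col) |>
    dplyr::summarise(days = list(.data$day),
                     counts = list(.data$nucleus_count),
                     .groups = "drop")
}

# log-linear fit for one series; returns a one-row tibble
fit_one_series <- function(days, counts, min_count) {
  usable <- counts >= max(min_count, 1L)   # zero counts cannot enter a log fit
  n_zero <- sum(counts == 0L)
  d <- days[usable]
  y <- log(counts[usable])
  base <- tibble(rate = NA_real_, doubling_time = NA_real_,
                 r_squared = NA_real_, n_points = length(d),
                 n_excluded = sum(!usable), reason = NA_character_)
  if (length(d) < 2L) {
    base$reason <- "fewer than 2 usable time points"
    return(base)
  }
  if (length(unique(y)) == 1L) {
    base$rate <- 0
    base$doubling_time <- Inf
    base$r_squared <- if (length(d) >= 3L) 1 else NA_real_
    return(base)
  }
  fit <- lm(y ~ d)
  r <- unname(coef(fit)[2])
  base$rate <- r
  base$doubling_time <- if (r > 0) log(2) / r else Inf
  if (length(d) >= 3L) {
    base$r_squared <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  }
  base
}

#' Fit exponential growth to per-feature time series
#'
#' Each series is fitted by least squares on (day, log count): the slope is
#' the growth rate per day and the doubling time is `log(2) / rate` (infinite
#' for non-positive rates). Zero counts are excluded from the log fit and
#' their exclusion recorded; series with fewer than two usable points return
#' a no-fit row with a reason. `r_squared` is reported only for fits with at
#' least three points.
#'
#' @param series Nested tibble from [join_timepoints()], or a raw
#'   count-record tibble (joined automatically).
#' @param min_count Minimum count for a point to enter the fit (default 1).
#' @return The input tibble with columns `rate`, `doubling_time`,
#'   `r_squared`, `n_points`, `n_excluded`, `reason` added.
#' @examples
#' recs <- tibble::tibble(well = 1L, grid_row = 1L, grid_col = 1L,
#'                        day = 1:4, nucleus_count = c(1L, 2L, 4L, 8L))
#' fit_growth(recs)   # rate = log(2), doubling time 1 day
#' @export
fit_growth <- function(series, min_count = 1L) {
  if ("nucleus_count" %in% names(series)) series <- join_timepoints(series)
  fits <- purrr::map2(series$days, series$counts, fit_one_series,
                      min_count = min_count)
  dplyr::bind_cols(series, dplyr::bind_rows(fits))
}

#' Fit a single growth curve
#'
#' Convenience wrapper around the same log-linear fit for one series.
#'
#' @param days,counts Aligned vectors, `days` strictly increasing.
#' @inheritParams fit_growth
#' @return An object of class `growth_fit` with [tidy()] and [glance()]
#'   methods.
#' @export
fit_exponential <- function(days, counts, min_count = 1L) {
  stopifnot(length(days) == length(counts), !is.unsorted(days, strictly = TRUE))
  out <- fit_one_series(days, counts, min_count)
  structure(list(days = days, counts = counts, fit = out),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  f <- x$fit
  if (is.na(f$rate)) {
    cat(sprintf("<growth_fit> no fit (%s)\n", f$reason))
  } else {
    cat(sprintf("<growth_fit> rate %.3f /day, doubling time %s days (n = %d)\n",
                f$rate,
                if (is.finite(f$doubling_time))
                  sprintf("%.2f", f$doubling_time) else "Inf",
                f$n_points))
  }
  invisible(x)
}

#' @rdname fit_exponential
#' @param x A `growth_fit` object.
#' @param ... Unused.
#' @export
tidy.growth_fit <- function(x, ...) {
  dplyr::select(x$fit, "rate", "doubling_time", "r_squared")
}

#' @rdname fit_exponential
#' @export
glance.growth_fit <- function(x, ...) {
  x$fit
}

#' Classify clones into growth categories
#'
#' Partitions features into low / intermediate / high growth on a chosen
#' statistic. Thresholds default to the tertiles of the statistic; explicit
#' thresholds `c(low_max, high_min)` override them. Values on a boundary go
#' to the higher class.
#'
#' @param fits Tibble from [fit_growth()] (needs `counts` list column for
#'   the final-count statistic, `rate` for the rate statistic).
#' @param statistic `"final_count"` (default) or `"rate"`.
#' @param thresholds Numeric `c(low_max, high_min)` with
#'   `low_max < high_min`, or `NULL` for tertiles.
#' @return `fits` with columns `statistic_value` and `growth_class` (ordered
#'   factor low < intermediate < high) added; zero rows in, zero rows out.
#' @export
classify_growth <- function(fits, statistic = c("final_count", "rate"),
                            thresholds = NULL) {
  statistic <- match.arg(statistic)
  if (nrow(fits) == 0L) {
    return(dplyr::mutate(
      fits, statistic_value = numeric(0),
      growth_class = factor(character(0),
                            levels = c("low", "intermediate", "high"),
                            ordered = TRUE)))
  }
  value <- switch(
    statistic,
    final_count = purrr::map_dbl(fits$counts, ~ as.numeric(tail(.x, 1L))),
    rate = fits$rate
  )
  if (is.null(thresholds)) {
    thresholds <- unname(stats::quantile(value, c(1 / 3, 2 / 3), na.rm = TRUE))
    if (thresholds[1] >= thresholds[2]) {
      # tied tertiles (heavily discrete statistic): values at the tie go to
      # the intermediate class
      thresholds[2] <- thresholds[1] +
        sqrt(.Machine$double.eps) * max(1, abs(thresholds[1]))
    }
  }
  if (length(thresholds) != 2L || !(thresholds[1] < thresholds[2])) {
    abort("`thresholds` must be c(low_max, high_min) with low_max < high_min.")
  }
  cls <- dplyr::case_when(
    value >= thresholds[2] ~ "high",
    value >= thresholds[1] ~ "intermediate",
    .default = "low"
  )
  dplyr::mutate(
    fits,
    statistic_value = value,
    growth_class = factor(cls, levels = c("low", "intermediate", "high"),
                          ordered = TRUE)
  )
}

#' Two-sample Student t-test between growth groups
#'
#' Pooled-variance Student t by default, with Welch's unequal-variance test
#' available by flag. When both groups are constant with equal means the
#' comparison is degenerate and `t = 0, p = 1` is returned by convention.
#'
#' @param a,b Numeric vectors, each with at least 2 finite values.
#' @param var_equal Pooled-variance Student test (default `TRUE`); `FALSE`
#'   gives Welch.
#' @param bonferroni_m Optional number of comparisons for a Bonferroni
#'   adjustment of the p value (default 1, no adjustment).
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `mean_a`,
#'   `mean_b`, `method`.
#' @export
compare_groups <- function(a, b, var_equal = TRUE, bonferroni_m = 1L) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L) {
    abort("Each group needs at least 2 finite values.")
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      inform("Both groups constant with equal means: t = 0, p = 1 by convention.")
      return(tibble(statistic = 0, df = NA_real_, p_value = 1,
                    mean_a = mean(a), mean_b = mean(b),
                    method = "degenerate"))
    }
    # constant but different means: separation is exact
    return(tibble(statistic = Inf * sign(mean(a) - mean(b)), df = NA_real_,
                  p_value = 0, mean_a = mean(a), mean_b = mean(b),
                  method = "degenerate"))
  }
  tt <- t.test(a, b, var.equal = var_equal)
  p <- min(1, unname(tt$p.value) * bonferroni_m)
  tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = p, mean_a = mean(a), mean_b = mean(b),
         method = tt$method)
}

#' Poisson clonal seeding statistics
#'
#' Seeding at limiting dilution puts a Poisson(`lambda`) number of cells on
#' each feature. Clonality requires high probability of 0 or 1 cell:
#' `P(0 or 1) = (1 + lambda) * exp(-lambda)`, and the expected number of
#' features with exactly one founder is `n_features * lambda * exp(-lambda)`.
#'
#' @param lambda Mean cells per feature (>= 0).
#' @param n_features Number of features seeded.
#' @return A one-row tibble: `lambda`, `n_features`, `p_zero_or_one`,
#'   `p_exactly_one`, `expected_clonal_features`, `expected_multi_features`.
#' @examples
#' poisson_seeding(1, 400)   # P(0 or 1) = 2/e
#' @export
poisson_seeding <- function(lambda, n_features) {
  assert_scalar_number(lambda, "lambda", min = 0)
  assert_scalar_number(n_features, "n_features", min = 1)
  p1 <- lambda * exp(-lambda)
  p01 <- (1 + lambda) * exp(-lambda)
  tibble(
    lambda = lambda,
    n_features = as.integer(n_features),
    p_zero_or_one = p01,
    p_exactly_one = p1,
    expected_clonal_features = n_features * p1,
    expected_multi_features = n_features * (1 - p01)
  )
}

#' Pick-list of features in a growth class
#'
#' @param classified Output of [classify_growth()].
#' @param class Growth class to select (default `"low"`, the class enriched
#'   for edited clones when the edit impairs growth).
#' @param path Optional CSV path to write the pick-list to.
#' @return A tibble `well`, `grid_row`, `grid_col` of selected features.
#' @export
pick_features <- function(classified, class = "low", path = NULL) {
  out <- classified |>
    dplyr::filter(.data$growth_class == class) |>
    dplyr::select("well", "grid_row", "grid_col")
  if (!is.null(path)) readr::write_csv(out, path)
  out
}
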