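records_for <- function(counts_by_feature, days = seq_along(counts_by_feature[[1]])) {
  purrr::imap_dfr(counts_by_feature, function(cts, i) {
    tibble::tibble(well = 1L, grid_row = as.integer(i), grid_col = 1L,
                   day = as.integer(days[seq_along(cts)]),
                   nucleus_count = as.integer(cts))
  })
}

test_that("joining preserves gaps and one series per feature", {
  recs <- records_for(list(c(1, 2, 4, 8, 16)))
  recs24 <- purrr::map_dfr(1:24, ~ dplyr::mutate(recs, grid_row = .x))
  series <- join_timepoints(recs24)
  expect_equal(nrow(series), 24L)
  expect_true(all(lengths(series$days) == 5L))

  gappy <- records_for(list(c(2, 3, 6)), days = c(1, 2, 4))
  s <- join_timepoints(gappy)
  expect_equal(s$days[[1]], c(1L, 2L, 4L))
  expect_equal(nrow(join_timepoints(recs[0, ])), 0L)
})

test_that("exact doubling fits rate log(2) with unit doubling time", {
  fit <- fit_exponential(1:4, c(1, 2, 4, 8))
  g <- glance(fit)
  expect_equal(g$rate, log(2), tolerance = 1e-10)
  expect_equal(g$doubling_time, 1.0, tolerance = 1e-10)
  expect_equal(g$r_squared, 1.0, tolerance = 1e-10)
})

test_that("constant counts give zero rate and infinite doubling time", {
  g <- glance(fit_exponential(1:4, c(5, 5, 5, 5)))
  expect_equal(g$rate, 0)
  expect_equal(g$doubling_time, Inf)
})

test_that("zero counts are excluded and sparse series refuse to fit", {
  g <- glance(fit_exponential(1:4, c(0, 0, 3, 6)))
  expect_equal(g$n_excluded, 2L)
  expect_equal(g$rate, log(2), tolerance = 1e-10)
  nof <- glance(fit_exponential(1:3, c(0, 0, 4)))
  expect_true(is.na(nof$rate))
  expect_match(nof$reason, "fewer than 2")
})

test_that("log-linear slope matches a brute-force grid minimiser", {
  set.seed(30)
  days <- 1:6
  counts <- round(3 * exp(0.45 * days) * exp(rnorm(6, 0, 0.15)))
  fit <- glance(fit_exponential(days, counts))
  # oracle: grid search over (intercept, slope) on squared log residuals
  grid_r <- seq(0, 1, by = 0.0005)
  sse <- vapply(grid_r, function(r) {
    a <- mean(log(counts) - r * days)
    sum((log(counts) - a - r * days)^2)
  }, numeric(1))
  expect_equal(fit$rate, grid_r[which.min(sse)], tolerance = 0.001)
})

test_that("classification is a deterministic three-way partition", {
  fits <- fit_growth(records_for(list(c(1, 1, 1), c(2, 4, 8), c(3, 9, 27),
                                      c(1, 2, 3), c(2, 2, 2), c(4, 16, 64))))
  cl <- classify_growth(fits, thresholds = c(4, 20))
  expect_equal(as.character(cl$growth_class),
               c("low", "intermediate", "high", "low", "low", "high"))
  # boundary values go to the higher class
  clb <- classify_growth(fits, thresholds = c(3, 64))
  expect_equal(as.character(clb$growth_class)[c(1, 4, 6)],
               c("low", "intermediate", "high"))
  expect_error(classify_growth(fits, thresholds = c(10, 5)), "thresholds")
  expect_equal(nrow(classify_growth(fits[0, ])), 0L)
})

test_that("all-equal statistics collapse into a single class", {
  fits <- fit_growth(records_for(rep(list(c(2, 4, 8)), 5)))
  cl <- classify_growth(fits, thresholds = c(1, 100))
  expect_equal(dplyr::n_distinct(cl$growth_class), 1L)
})

test_that("well-separated synthetic growth rates classify diagonally", {
  set.seed(31)
  mk <- function(rate, n) {
    params <- clone_sim_params(seeding_density_lambda = 1,
                               growth_rate_per_day = rate)
    simulate_clone_counts(n, params, n_days = 6)
  }
  truth_rates <- c(low = log(1.1), intermediate = log(1.5), high = log(2))
  sims <- purrr::imap(truth_rates, function(r, nm) {
    mk(r, 40) |>
      dplyr::rename(grid_row = feature, nucleus_count = true_count) |>
      dplyr::mutate(well = match(nm, names(truth_rates)), grid_col = 1L,
                    truth = nm)
  })
  recs <- dplyr::bind_rows(sims)
  fits <- fit_growth(dplyr::select(recs, well, grid_row, grid_col, day,
                                   nucleus_count))
  fits <- dplyr::filter(fits, !is.na(rate))
  cl <- classify_growth(fits, statistic = "rate",
                        thresholds = c(mean(truth_rates[1:2]),
                                       mean(truth_rates[2:3])))
  lv <- names(truth_rates)
  cm <- table(factor(lv[cl$well], levels = lv),
              factor(as.character(cl$growth_class), levels = lv))
  expect_gt(sum(diag(cm)) / sum(cm), 0.9)
})

test_that("the pooled t-test matches the closed-form hand computation", {
  a <- c(1, 2, 3)
  b <- c(2, 4, 9)
  out <- compare_groups(a, b)
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  p_hand <- 2 * pt(abs(t_hand), df = 4, lower.tail = FALSE)
  expect_equal(out$statistic, t_hand, tolerance = 1e-12)
  expect_equal(out$p_value, p_hand, tolerance = 1e-12)
  expect_equal(out$df, 4)
})

test_that("identical groups give t = 0, p = 1", {
  x <- c(1, 5, 9, 2)
  out <- compare_groups(x, x)
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)
  deg <- suppressMessages(compare_groups(c(3, 3), c(3, 3)))
  expect_equal(deg$p_value, 1)
})

test_that("null p values are approximately uniform", {
  set.seed(32)
  ps <- replicate(1000, compare_groups(rnorm(8), rnorm(8))$p_value)
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("Poisson seeding statistics follow the analytic formulae", {
  expect_equal(poisson_seeding(0, 10)$p_zero_or_one, 1)
  s1 <- poisson_seeding(1, 400)
  expect_equal(s1$p_zero_or_one, 2 / exp(1), tolerance = 1e-12)
  expect_equal(s1$expected_clonal_features, 400 / exp(1), tolerance = 1e-12)
  lams <- seq(0, 5, by = 0.25)
  p01 <- vapply(lams, function(l) poisson_seeding(l, 1)$p_zero_or_one,
                numeric(1))
  expect_true(all(diff(p01) < 0))
  expect_error(poisson_seeding(-1, 10), "lambda")
})

test_that("the join-fit-classify pipeline ignores record order", {
  set.seed(33)
  recs <- records_for(list(c(1, 2, 5, 9), c(2, 2, 3, 3), c(1, 4, 16, 60)))
  shuffled <- recs[sample(nrow(recs)), ]
  a <- classify_growth(fit_growth(recs), thresholds = c(4, 30))
  b <- classify_growth(fit_growth(shuffled), thresholds = c(4, 30))
  expect_equal(a, b)
})
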