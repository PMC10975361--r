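test_that("EDA per-station statistics match hand computation", {
  data <- tibble::tibble(station_id = 1L, time_index = 1:4,
                         value = c(1, 2, 3, 4))
  s <- eda_summary(data)
  ps <- s$per_station
  expect_equal(ps$mean, 2.5)
  expect_equal(ps$sd, sd(c(1, 2, 3, 4)))
  expect_equal(round(ps$sd, 4), 1.2910)
  expect_equal(ps$min, 1)
  expect_equal(ps$max, 4)
})

test_that("Kruskal-Wallis statistic is zero for identical groups", {
  data <- tibble::tibble(
    station_id = rep(1:2, each = 5),
    time_index = rep(1:5, 2),
    value = rep(c(3, 1, 4, 1, 5), 2)
  )
  s <- eda_summary(data)
  expect_equal(s$kw$statistic, 0, tolerance = 1e-12)
})

test_that("pooled K-S accepts a normal sample of the study size", {
  set.seed(61)
  data <- tibble::tibble(
    station_id = rep(1:70, each = 88),
    time_index = rep(1:88, 70),
    value = rnorm(6160)
  )
  s <- eda_summary(data)
  expect_gt(s$ks$p, 0.05)
})

test_that("log10 transform inverts exactly and reduces lognormal skewness", {
  fx <- toy_series()
  back <- untransform_log10(transform_log10(fx$data))
  expect_equal(back$value, fx$data$value, tolerance = 1e-12)
  expect_equal(transform_log10(tibble::tibble(
    station_id = 1L, time_index = 1L, value = 100
  ))$value, 2)
  bad <- tibble::tibble(station_id = 1:2, time_index = 1, value = c(1, -3))
  expect_error(transform_log10(dplyr::bind_rows(bad, dplyr::mutate(bad, time_index = 2L))),
               "positive")
  set.seed(8)
  raw <- 10^rnorm(2000, 1, 0.4)
  expect_lt(moment_skewness(log10(raw)), moment_skewness(raw))
})

test_that("trend decomposition identity holds for every kind", {
  sim <- simulate_pm25(n_rows = 4, n_cols = 4, n_times = 24, seed = 19)
  dl <- transform_log10(sim$data)
  for (kind in c("constant", "linear_surface", "tensor_spline")) {
    fit <- fit_trend(dl, sim$stations, kind = kind, k_space = 4, k_time = 6)
    recomposed <- fit$fitted$value + fit$residuals$value
    expect_lt(max(abs(recomposed - dl$value)), 1e-10)
  }
})

test_that("constant trend is the grand mean; representable signals fit exactly", {
  fx <- toy_series(n_times = 8)
  dl <- fx$data
  fit <- fit_trend(dl, fx$stations, kind = "constant")
  expect_equal(unique(round(fit$fitted$value, 10)), round(mean(dl$value), 10))
  # a linear function of lon, lat, month is inside the linear-surface span
  lin <- dplyr::inner_join(dl[, c("station_id", "time_index")],
                           fx$stations, by = "station_id")
  lin$value <- 1 + 0.5 * lin$lon - 0.2 * lin$lat + 0.1 * lin$time_index
  fit2 <- fit_trend(lin[, c("station_id", "time_index", "value")],
                    fx$stations, kind = "linear_surface")
  expect_lt(max(abs(fit2$residuals$value)), 1e-8)
})

test_that("tensor-spline GCV never exceeds the linear-surface GCV", {
  sim <- simulate_pm25(n_rows = 4, n_cols = 5, n_times = 24, seed = 23)
  dl <- transform_log10(sim$data)
  f_lin <- fit_trend(dl, sim$stations, kind = "linear_surface")
  f_ten <- fit_trend(dl, sim$stations, kind = "tensor_spline", k_space = 4, k_time = 8)
  expect_lte(f_ten$gcv, f_lin$gcv * (1 + 1e-8))
})

test_that("the fitted trend recovers a known synthetic trend", {
  sim <- simulate_pm25(seed = 20240225)
  dl <- transform_log10(sim$data)
  fit <- fit_trend(dl, sim$stations, kind = "tensor_spline")
  true_trend <- log10(sim$trend$value)
  # the spatially correlated log-scale noise is partly confounded with the
  # month effect, which caps any smoother near cor ~0.93 on this field: a
  # saturated station + month two-way fit of the same data reaches 0.926
  oracle <- lm(dl$value ~ factor(dl$station_id) + factor(dl$time_index))
  expect_gte(cor(fit$fitted$value, true_trend),
             cor(fitted(oracle), true_trend) - 0.01)
  expect_gte(cor(fit$fitted$value, true_trend), 0.90)
  # the station-mean spatial trend itself is recovered almost exactly
  sm_fit <- tapply(fit$fitted$value, dl$station_id, mean)
  sm_true <- tapply(true_trend, dl$station_id, mean)
  expect_gte(cor(sm_fit, sm_true), 0.95)
})

test_that("basis dimensions beyond the data support error", {
  fx <- toy_series()
  expect_error(fit_trend(fx$data, fx$stations, kind = "tensor_spline",
                         k_space = 25), "k_space")
})

test_that("residual diagnostics flag degenerate and heteroscedastic residuals", {
  fx <- toy_series(n_times = 8)
  lin <- dplyr::inner_join(fx$data[, c("station_id", "time_index")],
                           fx$stations, by = "station_id")
  lin$value <- 1 + 0.5 * lin$lon - 0.2 * lin$lat + 0.1 * lin$time_index
  perfect <- fit_trend(lin[, c("station_id", "time_index", "value")],
                       fx$stations, kind = "linear_surface")
  expect_true(residual_diagnostics(perfect)$degenerate)

  # sd of noise proportional to fitted value: positive |resid| ~ fitted slope
  set.seed(71)
  het <- lin
  het$value <- het$value + rnorm(nrow(het), 0, 0.2 * het$value)
  fit_het <- fit_trend(het[, c("station_id", "time_index", "value")],
                       fx$stations, kind = "linear_surface")
  dg <- residual_diagnostics(fit_het)
  expect_gt(dg$het_slope, 0)
  expect_lt(dg$het_p, 0.05)
})

test_that("K-S on well-specified residuals passes in at least 90% of seeds", {
  fx <- toy_series(n_rows = 4, n_cols = 4, n_times = 10)
  lin <- dplyr::inner_join(fx$data[, c("station_id", "time_index")],
                           fx$stations, by = "station_id")
  base <- 1 + 0.5 * lin$lon - 0.2 * lin$lat + 0.1 * lin$time_index
  pass <- vapply(1:50, function(s) {
    set.seed(200 + s)
    d <- tibble::tibble(station_id = lin$station_id,
                        time_index = lin$time_index,
                        value = base + rnorm(nrow(lin)))
    fit <- fit_trend(d, fx$stations, kind = "linear_surface")
    residual_diagnostics(fit)$ks_p > 0.05
  }, logical(1))
  expect_gte(mean(pass), 0.9)
})

test_that("detrending escalation takes the documented branches", {
  # already-normal data: no transformation
  fx <- toy_series(n_rows = 4, n_cols = 4, n_times = 10)
  lin <- dplyr::inner_join(fx$data[, c("station_id", "time_index")],
                           fx$stations, by = "station_id")
  set.seed(301)
  normal <- tibble::tibble(station_id = lin$station_id,
                           time_index = lin$time_index,
                           value = 100 + rnorm(nrow(lin)))
  esc1 <- detrend_escalate(normal, fx$stations)
  expect_equal(esc1$level, "raw")
  expect_match(esc1$log[2], "passes normality")

  # strongly skewed synthetic field escalates past the raw level
  sim <- simulate_pm25(n_rows = 5, n_cols = 6, n_times = 60, sill_log = 0.03,
                       seed = 31)
  esc2 <- detrend_escalate(sim$data, sim$stations, k_space = 4)
  expect_true(esc2$level %in% c("log10", "linear_surface", "tensor_spline"))
  expect_gte(length(esc2$log), 3)
})
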