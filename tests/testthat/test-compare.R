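test_that("identical method columns give a zero Friedman statistic", {
  m <- matrix(rep(c(1, 2, 3, 4, 5), 3), ncol = 3)
  colnames(m) <- c("a", "b", "c")
  cmp <- friedman_nemenyi(m)
  expect_equal(cmp$friedman$statistic, 0)
  expect_equal(cmp$friedman$p, 1)
  expect_equal(diag(cmp$nemenyi_p), c(a = 1, b = 1, c = 1))
})

test_that("a uniformly dominant method is detected by Friedman and Nemenyi", {
  set.seed(73)
  n <- 20
  base <- matrix(runif(n * 3, 5, 10), n, 3)
  colnames(base) <- c("a", "b", "c")
  base[, "b"] <- base[, "b"] - 6  # method b uniformly best
  cmp <- friedman_nemenyi(base)
  expect_lt(cmp$friedman$p, 0.01)
  expect_lt(cmp$nemenyi_p["b", "a"], 0.05)
  expect_lt(cmp$nemenyi_p["b", "c"], 0.05)
  expect_equal(cmp$nemenyi_p, t(cmp$nemenyi_p))
  # oracle: mean ranks computed directly
  expect_equal(cmp$mean_ranks, colMeans(t(apply(base, 1, rank))))
  # rank-based: monotone transformation leaves the statistic unchanged
  cmp2 <- friedman_nemenyi(exp(base / 3))
  expect_equal(cmp2$friedman$statistic, cmp$friedman$statistic)
})

test_that("two-method Friedman reduces to the matched-pairs rank form", {
  set.seed(79)
  n <- 15
  m <- cbind(a = runif(n), b = runif(n))
  cmp <- friedman_nemenyi(m)
  # closed form for k = 2 without ties: chi2 = (sum of rank diffs)^2 / n
  s <- sum(apply(m, 1, function(r) rank(r)[1] - rank(r)[2]))
  expect_equal(cmp$friedman$statistic, s^2 / n)
})

test_that("reduction percentages recompute from the column means", {
  m <- cbind(a = c(2, 4), b = c(1, 1))
  cmp <- friedman_nemenyi(m)
  expect_equal(cmp$reduction_pct["a", "b"], 100 * (3 - 1) / 3)
  expect_equal(cmp$reduction_pct["a", "a"], 0)
})

test_that("Moran's I and Geary's C match the alternating-line hand values", {
  w <- matrix(0, 4, 4)
  for (i in 1:3) { w[i, i + 1] <- 1; w[i + 1, i] <- 1 }
  vals <- c(1, -1, 1, -1)
  mi <- morans_i(vals, w, n_perm = 0)
  expect_equal(mi$statistic, -1)
  expect_equal(mi$expectation, -1 / 3)
  gc <- gearys_c(vals, w, n_perm = 0)
  expect_equal(gc$statistic, 1.5)
})

test_that("autocorrelation statistics match a brute-force double loop", {
  set.seed(83)
  st <- make_grid(3, 4, lon0 = 0, lat0 = 2, spacing_lon = 1, spacing_lat = 1)
  w <- spatial_weights(st, "idw")
  x <- rnorm(12)
  z <- x - mean(x)
  n <- 12; s0 <- sum(w)
  manual_i <- 0; manual_c <- 0
  for (i in 1:n) for (j in 1:n) {
    manual_i <- manual_i + w[i, j] * z[i] * z[j]
    manual_c <- manual_c + w[i, j] * (x[i] - x[j])^2
  }
  expect_equal(morans_i(x, w, n_perm = 0)$statistic,
               (n / s0) * manual_i / sum(z^2))
  expect_equal(gearys_c(x, w, n_perm = 0)$statistic,
               ((n - 1) / (2 * s0)) * manual_c / sum(z^2))
})

test_that("iid values match the permutation-null expectations", {
  set.seed(89)
  st <- make_grid(4, 5, lon0 = 0, lat0 = 3, spacing_lon = 1, spacing_lat = 1)
  w <- spatial_weights(st, "idw")
  is <- replicate(200, morans_i(rnorm(20), w, n_perm = 0)$statistic)
  cs <- replicate(200, gearys_c(rnorm(20), w, n_perm = 0)$statistic)
  expect_equal(mean(is), -1 / 19, tolerance = 0.5)  # Monte-Carlo error band
  expect_lt(abs(mean(is) - (-1 / 19)), 3 * sd(is) / sqrt(200))
  expect_lt(abs(mean(cs) - 1), 3 * sd(cs) / sqrt(200))
})

test_that("smooth gradients show positive spatial autocorrelation", {
  st <- make_grid(4, 5, lon0 = 0, lat0 = 3, spacing_lon = 1, spacing_lat = 1)
  w <- spatial_weights(st, "knn", k = 4)
  vals <- st$lon + st$lat
  expect_lt(gearys_c(vals, w, n_perm = 0)$statistic, 1)
  expect_gt(morans_i(vals, w, n_perm = 0)$statistic, 0)
})

test_that("permutation p-values are seeded and reproducible", {
  set.seed(97)
  st <- make_grid(3, 3, lon0 = 0, lat0 = 2, spacing_lon = 1, spacing_lat = 1)
  w <- spatial_weights(st)
  x <- rnorm(9)
  p1 <- morans_i(x, w, n_perm = 199, seed = 7)$p
  p2 <- morans_i(x, w, n_perm = 199, seed = 7)$p
  expect_equal(p1, p2)
})

test_that("benchmark assembles consistent reports deterministically", {
  sim <- simulate_pm25(n_rows = 4, n_cols = 4, n_times = 10, seed = 101)
  b1 <- benchmark_methods(sim$data, sim$stations, methods = c("idw", "bss"),
                          seed = 5, idw_beta = 2, n_perm = 99)
  b2 <- benchmark_methods(sim$data, sim$stations, methods = c("idw", "bss"),
                          seed = 5, idw_beta = 2, n_perm = 99)
  expect_equal(b1$metrics, b2$metrics)
  expect_equal(b1$autocorr, b2$autocorr)
  # reduction table recomputes from the per-station metric means
  red <- b1$comparisons$mae$reduction_pct["idw", "bss"]
  m_idw <- mean(b1$metrics$idw$mae); m_bss <- mean(b1$metrics$bss$mae)
  expect_equal(red, 100 * (m_idw - m_bss) / m_idw)
})

test_that("near-noise-free planar fields leave no method differences", {
  fx <- toy_series(n_rows = 4, n_cols = 5, n_times = 8, d = 1)
  b <- benchmark_methods(fx$data, fx$stations, methods = c("idw", "bss"),
                         idw_beta = 2, n_perm = 0)
  # both methods are near-exact away from corners; Friedman may see rank
  # differences of numerically tiny errors, so compare magnitudes instead:
  # errors are a few percent of the mean level at most
  level <- mean(fx$data$value)
  expect_lt(mean(b$metrics$bss$mae), 0.05 * level)
  expect_lt(mean(b$metrics$idw$mae), 0.05 * level)
})

test_that("edge-gradient fields favour buffered splines over IDW at edges", {
  sim <- simulate_pm25(gradient_lon = 10, gradient_lat = -6, sill_log = 0.002,
                       outlier_rate = 0, seed = 404)
  st <- sim$stations
  b <- benchmark_methods(sim$data, st, methods = c("idw", "bss"), n_perm = 0)
  edge <- st$station_id[st$grid_row %in% c(0, 6) | st$grid_col %in% c(0, 9)]
  mae_idw <- mean(b$metrics$idw$mae[b$metrics$idw$station_id %in% edge])
  mae_bss <- mean(b$metrics$bss$mae[b$metrics$bss$station_id %in% edge])
  expect_lt(mae_bss, mae_idw)
})
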