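# Independent brute-force IDW oracle used throughout this file.
idw_oracle <- function(lon, lat, value, qlon, qlat, beta,
                       convention = "great_circle_km") {
  d <- point_distance(lon, lat, qlon, qlat, convention)
  if (any(d == 0)) return(mean(value[d == 0]))
  sum(value / d^beta) / sum(1 / d^beta)
}

test_that("idw_predict matches hand evaluations of the weighting formula", {
  # single neighbor: weights normalize to 1
  one <- tibble::tibble(lon = 3, lat = 1, value = 7.3)
  for (b in c(1, 2, 7)) {
    expect_equal(idw_predict(one, tibble::tibble(lon = 0, lat = 0), beta = b), 7.3)
  }
  # two equidistant neighbors: symmetric average
  two <- tibble::tibble(lon = c(-1, 1), lat = 0, value = c(10, 20))
  for (b in c(1, 2.5, 6)) {
    expect_equal(idw_predict(two, tibble::tibble(lon = 0, lat = 0), beta = b), 15)
  }
  # distances (1, 2, 4), values (10, 20, 40), beta = 2:
  # (10/1 + 20/4 + 40/16) / (1 + 1/4 + 1/16) = 17.5 / 1.3125 = 13.333...
  three <- tibble::tibble(lon = c(1, 2, 4), lat = 0, value = c(10, 20, 40))
  expect_equal(
    idw_predict(three, tibble::tibble(lon = 0, lat = 0),
                beta = 2, convention = "euclidean_degrees"),
    17.5 / 1.3125
  )
  expect_equal(17.5 / 1.3125, 13.33333, tolerance = 1e-6)
})

test_that("a target coinciding with a neighbor returns its value exactly", {
  pts <- tibble::tibble(lon = c(0, 1, 2), lat = 0, value = c(5, 9, 13))
  expect_equal(
    idw_predict(pts, tibble::tibble(lon = 1, lat = 0), beta = 3), 9
  )
})

test_that("weights are convex: predictions bounded by neighbor range", {
  set.seed(21)
  for (rep in 1:20) {
    pts <- tibble::tibble(lon = runif(6), lat = runif(6), value = rnorm(6))
    q <- tibble::tibble(lon = runif(1), lat = runif(1))
    p <- idw_predict(pts, q, beta = runif(1, 0.5, 8))
    expect_gte(p, min(pts$value) - 1e-12)
    expect_lte(p, max(pts$value) + 1e-12)
  }
})

test_that("large beta approaches nearest-neighbor prediction", {
  set.seed(33)
  pts <- tibble::tibble(lon = runif(8), lat = runif(8), value = rnorm(8))
  q <- tibble::tibble(lon = 0.31, lat = 0.57)
  d <- point_distance(pts$lon, pts$lat, q$lon, q$lat)
  expect_equal(idw_predict(pts, q, beta = 50), pts$value[which.min(d)],
               tolerance = 0.01)
})

test_that("LOOCV equals brute-force per-fold recomputation", {
  sim <- simulate_pm25(n_rows = 5, n_cols = 5, n_times = 6, seed = 2)
  z <- series_matrix(sim$data)
  folds <- idw_loocv(sim$data, sim$stations, beta = 2)
  for (k in c(1, 7, 25)) {
    for (t in c(1, 6)) {
      manual <- idw_oracle(
        sim$stations$lon[-k], sim$stations$lat[-k], z[-k, t],
        sim$stations$lon[k], sim$stations$lat[k], beta = 2
      )
      got <- folds$predicted[folds$station_id == k & folds$time_index == t]
      expect_equal(got, manual, tolerance = 1e-12)
    }
  }
})

test_that("spatially constant fields are predicted exactly", {
  fx <- constant_series(value = 42)
  folds <- idw_loocv(fx$data, fx$stations, beta = 4)
  expect_equal(folds$predicted, folds$observed, tolerance = 1e-12)
})

test_that("middle of three collinear equispaced stations gets the end mean", {
  stations <- tibble::tibble(station_id = 1:3, lon = c(0, 1, 2), lat = 0)
  data <- tidyr::expand_grid(station_id = 1:3, time_index = 1:2)
  data$value <- rep(c(4, 8, 12), each = 2) + rep(c(0, 1), 3)
  folds <- idw_loocv(data, stations, beta = 3.7)
  mid <- folds[folds$station_id == 2, ]
  ends <- dplyr::summarise(
    dplyr::group_by(folds[folds$station_id != 2, ], time_index),
    m = mean(observed)
  )
  expect_equal(mid$predicted, ends$m[match(mid$time_index, ends$time_index)])
})

test_that("beta selection recovers the generating power and reports true scores", {
  # construct a field whose held-out values are exactly the beta = 3 IDW
  # predictions of the remaining stations
  sim <- simulate_pm25(n_rows = 4, n_cols = 5, n_times = 6, seed = 8)
  z <- series_matrix(sim$data)
  st <- sim$stations
  d <- pairwise_distance(st)
  # one smoothing pass: every station's value becomes the beta = 3
  # prediction of the other stations' values
  z2 <- z
  for (k in seq_len(nrow(z))) {
    w <- d[k, -k]^-3
    z2[k, ] <- drop((w / sum(w)) %*% z[-k, , drop = FALSE])
  }
  data3 <- matrix_series(z2)
  opt <- idw_optimize(data3, st, betas = 1:10)
  expect_equal(opt$beta, 3)
  # reported table matches an independent pooled-RMSE recomputation
  for (b in c(1, 3, 7)) {
    folds <- idw_loocv(data3, st, beta = b)
    expect_equal(opt$scores$rmse[opt$scores$beta == b],
                 sqrt(mean((folds$observed - folds$predicted)^2)),
                 tolerance = 1e-12)
  }
})

test_that("constant field ties are broken toward the smallest beta", {
  fx <- constant_series(value = 7)
  opt <- idw_optimize(fx$data, fx$stations, betas = 1:5)
  expect_true(all(opt$scores$rmse < 1e-12))
  expect_equal(opt$beta, 1)
})
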