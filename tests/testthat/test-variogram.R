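test_that("marginal variograms honour nugget, monotonicity and saturation", {
  for (fam in c("exponential", "spherical", "gaussian", "matern")) {
    m <- vgm_model(fam, range = 100, nugget = 0.2)
    h <- seq(0, 1000, by = 10)
    g <- vgm_eval(m, h)
    expect_equal(g[1], 0.2)
    expect_true(all(diff(g) >= -1e-12))
    expect_lt(abs(g[length(g)] - 1), 1e-3)
    expect_true(all(g >= 0 & g <= 1))
  }
  # spherical reaches its sill exactly at the range
  sph <- vgm_model("spherical", range = 50)
  expect_equal(vgm_eval(sph, c(50, 80, 200)), c(1, 1, 1))
  # exponential correlation at lag = range is exp(-1)
  expo <- vgm_model("exponential", range = 200)
  expect_equal(1 - vgm_eval(expo, 200), exp(-1))
})

test_that("separable variogram evaluates the product-sum identity", {
  spatial <- vgm_model("exponential", range = 100)
  temporal <- vgm_model("exponential", range = 3)
  m <- sep_vgm(2, spatial, temporal)
  # hand evaluation: gs = gt = 0.5 -> 2 * (0.5 + 0.5 - 0.25) = 1.5
  h_half <- -100 * log(0.5)   # gs(h) = 0.5
  t_half <- -3 * log(0.5)
  expect_equal(sep_vgm_eval(m, h_half, t_half), 1.5)
  # reductions
  expect_equal(sep_vgm_eval(m, 0, 5), m$sill * vgm_eval(temporal, 5))
  big <- sep_vgm_eval(m, 1e7, 1e7)
  expect_equal(big, 2, tolerance = 1e-6)
  # covariance identity sill - C = gamma at random lags
  set.seed(3)
  hh <- runif(20, 0, 500); tt <- runif(20, 0, 12)
  expect_equal(sep_cov(m, hh, tt), m$sill - sep_vgm_eval(m, hh, tt))
  # nugget composition at the origin: sill * (ns + nt - ns * nt)
  mn <- sep_vgm(2, vgm_model("exponential", 100, nugget = 0.2),
                vgm_model("exponential", 3, nugget = 0.1))
  expect_equal(sep_vgm_eval(mn, 0, 0), 2 * (0.2 + 0.1 - 0.02))
  expect_error(sep_vgm_eval(m, -1, 0), "non-negative")
})

test_that("empirical variogram matches the two-station hand computation", {
  # z11 = 0, z12 = 2, z21 = 1, z22 = 3: pure spatial semivariance
  # ((0-1)^2 + (2-3)^2) / 2 / 2 = 0.5
  stations <- tibble::tibble(station_id = 1:2, lon = c(0, 1), lat = 0)
  data <- tibble::tibble(
    station_id = c(1L, 1L, 2L, 2L), time_index = c(1L, 2L, 1L, 2L),
    value = c(0, 2, 1, 3)
  )
  emp <- empirical_st_variogram(data, stations, n_spatial_bins = 2, max_tlag = 1)
  spatial0 <- emp[emp$tau == 0 & emp$h > 0, ]
  expect_equal(spatial0$gamma, 0.5)
  # pure temporal lag 1: mean of (0-2)^2, (1-3)^2 over stations / 2 = 2
  temporal1 <- emp[emp$tau == 1 & emp$h == 0, ]
  expect_equal(temporal1$gamma, 2)
})

test_that("white-noise residuals give a flat variogram at the variance", {
  set.seed(55)
  stations <- make_grid(5, 5, lon0 = 0, lat0 = 4, spacing_lon = 1, spacing_lat = 1)
  z <- matrix(rnorm(25 * 200), 25, 200)
  dimnames(z) <- list(1:25, 1:200)
  emp <- empirical_st_variogram(matrix_series(z), stations,
                                n_spatial_bins = 5, max_tlag = 3)
  expect_true(all(abs(emp$gamma - 1) < 0.2))
})

test_that("time-constant residuals repeat the spatial pattern at all lags", {
  stations <- make_grid(3, 3, lon0 = 0, lat0 = 2, spacing_lon = 1, spacing_lat = 1)
  set.seed(9)
  profile <- rnorm(9)
  z <- matrix(profile, 9, 10)
  dimnames(z) <- list(1:9, 1:10)
  emp <- empirical_st_variogram(matrix_series(z), stations,
                                n_spatial_bins = 4, max_tlag = 2)
  g0 <- emp[emp$tau == 0 & emp$h > 0, c("h", "gamma")]
  g2 <- emp[emp$tau == 2 & emp$h > 0, c("h", "gamma")]
  shared <- dplyr::inner_join(g0, g2, by = "h")
  expect_equal(shared$gamma.x, shared$gamma.y, tolerance = 1e-12)
})

test_that("noise-free separable surfaces are recovered within 1%", {
  truth <- sep_vgm(0.8, vgm_model("exponential", 150, nugget = 0.1),
                   vgm_model("exponential", 4, nugget = 0.05))
  hs <- seq(20, 600, length.out = 10)
  emp <- tidyr::expand_grid(h = hs, tau = 0:5)
  emp$gamma <- sep_vgm_eval(truth, emp$h, emp$tau)
  emp$npairs <- 100
  class(emp) <- c("emp_st_variogram", class(emp))
  fit <- fit_separable(emp, "exponential", "exponential")
  expect_equal(fit$sill, 0.8, tolerance = 0.01)
  expect_equal(fit$spatial$range, 150, tolerance = 0.01)
  expect_equal(fit$temporal$range, 4, tolerance = 0.01)
  # individual nuggets enter the separable model only through the product
  # (1 - ns)(1 - nt), which is what the data identify
  expect_equal((1 - fit$spatial$nugget) * (1 - fit$temporal$nugget),
               (1 - 0.1) * (1 - 0.05), tolerance = 0.01)
  expect_lt(fit$fit_mse, 1e-8)
})

test_that("pair-count weighting changes the fit on unbalanced bins", {
  truth <- sep_vgm(1, vgm_model("exponential", 100), vgm_model("exponential", 3))
  emp <- tidyr::expand_grid(h = seq(10, 500, length.out = 8), tau = 0:3)
  emp$gamma <- sep_vgm_eval(truth, emp$h, emp$tau)
  # corrupt one far bin and give it overwhelming weight
  emp$gamma[emp$h > 400 & emp$tau == 0] <- 2
  emp$npairs <- ifelse(emp$h > 400 & emp$tau == 0, 1e6, 5)
  class(emp) <- c("emp_st_variogram", class(emp))
  f_w <- fit_separable(emp, "exponential", "exponential", weights = "npairs")
  f_e <- fit_separable(emp, "exponential", "exponential", weights = "equal")
  expect_gt(abs(f_w$sill - f_e$sill), 0.05)
})

test_that("parameters of a simulated separable GP are recovered", {
  stations <- make_grid(7, 10)
  truth <- sep_vgm(0.01, vgm_model("exponential", 200),
                   vgm_model("exponential", 3))
  z <- simulate_separable_gp(stations, 88, truth$spatial, truth$temporal,
                             sill = 0.01, seed = 314)
  emp <- empirical_st_variogram(matrix_series(z), stations,
                                n_spatial_bins = 10, max_tlag = 6)
  fit <- fit_separable(emp, "exponential", "exponential")
  expect_equal(fit$spatial$range, 200, tolerance = 0.3)
  expect_equal(fit$temporal$range, 3, tolerance = 0.3)
  expect_equal(fit$sill, 0.01, tolerance = 0.25)
})

test_that("kriging is exact at data points with weights summing to one", {
  sim <- simulate_pm25(n_rows = 4, n_cols = 4, n_times = 12, seed = 17)
  resid <- dplyr::mutate(sim$data, value = log10(value) - mean(log10(value)))
  model <- sep_vgm(0.01, vgm_model("exponential", 150),
                   vgm_model("exponential", 3))
  k <- 6
  kr <- krige_st(resid, sim$stations, model,
                 lon = sim$stations$lon[k], lat = sim$stations$lat[k],
                 times = c(1, 5, 12))
  z <- series_matrix(resid)
  expect_equal(kr$pred, z[k, c(1, 5, 12)], ignore_attr = TRUE, tolerance = 1e-8)
  expect_true(all(kr$var >= 0))
  expect_true(all(kr$var < 1e-8))
})

test_that("kriging at a new site matches an independent dense solve", {
  # 3 stations, 1 month: the system is small enough to solve from scratch
  stations <- tibble::tibble(station_id = 1:3, lon = c(0, 1, 0), lat = c(0, 0, 1))
  data <- tibble::tibble(station_id = 1:3, time_index = 1L,
                         value = c(1.0, 2.0, 4.0))
  model <- sep_vgm(2, vgm_model("exponential", 100),
                   vgm_model("exponential", 3))
  target <- c(lon = 0.4, lat = 0.3)
  kr <- krige_st(data, stations, model, lon = target["lon"], lat = target["lat"],
                 times = 1, k_t = 1)
  # independent construction of the ordinary kriging system
  d <- pairwise_distance(stations)
  C <- model$sill * (1 - vgm_eval(model$spatial, d))
  c0 <- model$sill * (1 - vgm_eval(model$spatial,
                                   distance_to(stations, target["lon"], target["lat"])))
  A <- rbind(cbind(C, 1), c(1, 1, 1, 0))
  wl <- solve(A, c(c0, 1))
  expect_equal(kr$pred, sum(wl[1:3] * data$value), tolerance = 1e-10)
  expect_equal(sum(wl[1:3]), 1, tolerance = 1e-12)
  expect_equal(kr$var, model$sill - sum(wl[1:3] * c0) - wl[4], tolerance = 1e-10)
})

test_that("back-transform applies the documented correction factor", {
  expect_equal(back_transform(2, 0), 100)
  expect_equal(back_transform(1, 0.04), 10 * 10^0.02)
  expect_equal(round(back_transform(1, 0.04), 4), 10.4713)
  expect_equal(back_transform(1, 0.04, exact = TRUE), 10 * 10^(log(10) * 0.02))
  # factor is never below one
  set.seed(2)
  s2 <- runif(50, 0, 0.5)
  expect_true(all(back_transform(0, s2) >= 1))
  expect_error(back_transform(1, -0.1), "non-negative")
})
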