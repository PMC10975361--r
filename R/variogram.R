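# Separable spatio-temporal variogram machinery. Marginal variograms are
# standardized: gamma_bar(0) = nugget fraction, gamma_bar -> 1 at large lag.
# The separable model combines them as
#   gamma_sep(h, tau) = sill * (gs(h) + gt(tau) - gs(h) * gt(tau)),
# whose covariance companion C = sill - gamma_sep factorizes as
# sill * (1 - gs(h)) * (1 - gt(tau)) -- a Kronecker product over stations and
# months, which the kriging solver exploits.

VGM_FAMILIES <- c("exponential", "spherical", "gaussian", "matern")

#' Define a standardized marginal variogram model
#'
#' @param family One of `"exponential"`, `"spherical"`, `"gaussian"`,
#'   `"matern"`.
#' @param range Range parameter (km for spatial, months for temporal). For the
#'   exponential family the correlation at lag = range is `exp(-1)`; the
#'   spherical model reaches its sill exactly at `range`.
#' @param nugget Nugget fraction in `[0, 1)`: the standardized variogram jumps
#'   to this value at lag 0+.
#' @param nu Matern smoothness (ignored by other families).
#' @return An object of class `vgm_marginal`.
#' @examples
#' vgm_eval(vgm_model("exponential", 200), c(0, 200))  # 0, 1 - exp(-1)
#' @export
vgm_model <- function(family = VGM_FAMILIES, range, nugget = 0, nu = 1.5) {
  family <- match.arg(family)
  stopifnot(range > 0, nugget >= 0, nugget < 1, nu > 0)
  structure(list(family = family, range = range, nugget = nugget, nu = nu),
            class = "vgm_marginal")
}

#' @export
print.vgm_marginal <- function(x, ...) {
  cat(sprintf("%s variogram: range %.4g, nugget %.3g", x$family, x$range, x$nugget))
  if (x$family == "matern") cat(sprintf(", nu %.3g", x$nu))
  cat("\n")
  invisible(x)
}

#' Evaluate a standardized marginal variogram
#'
#' @param model A [vgm_model()].
#' @param h Non-negative lags (vector or matrix; shape preserved).
#' @return Standardized semivariance in `[0, 1]`; equals `model$nugget` at
#'   `h = 0` and tends to 1 at large lags.
#' @export
vgm_eval <- function(model, h) {
  if (any(h < 0)) abort("Lags must be non-negative.")
  rho <- vgm_correlation(model, h)
  g <- model$nugget + (1 - model$nugget) * (1 - rho)
  if (is.matrix(h)) dim(g) <- dim(h)
  g
}

# Pure correlation function of the family (1 at h = 0, no nugget).
vgm_correlation <- function(model, h) {
  r <- model$range
  switch(model$family,
    exponential = exp(-h / r),
    gaussian = exp(-(h / r)^2),
    spherical = ifelse(h < r, 1 - (1.5 * (h / r) - 0.5 * (h / r)^3), 0),
    matern = {
      s <- sqrt(2 * model$nu) * h / r
      out <- ifelse(
        s > 0,
        (2^(1 - model$nu) / gamma(model$nu)) * s^model$nu * besselK(pmax(s, 1e-12), model$nu),
        1
      )
      pmin(out, 1)
    }
  )
}

#' Define a separable spatio-temporal variogram
#'
#' @param sill Joint sill (variance of the modelled field; log10 units squared
#'   when fitted to log residuals).
#' @param spatial,temporal Marginal [vgm_model()] objects (range in km and
#'   months respectively).
#' @return An object of class `separable_variogram`.
#' @export
sep_vgm <- function(sill, spatial, temporal) {
  stopifnot(sill >= 0, inherits(spatial, "vgm_marginal"), inherits(temporal, "vgm_marginal"))
  structure(list(sill = sill, spatial = spatial, temporal = temporal),
            class = "separable_variogram")
}

#' @export
print.separable_variogram <- function(x, ...) {
  cat(sprintf("Separable spatio-temporal variogram (sill %.4g)\n", x$sill))
  cat("  spatial : "); print(x$spatial)
  cat("  temporal: "); print(x$temporal)
  if (!is.null(x$fit_mse)) cat(sprintf("  WLS fit MSE %.4g\n", x$fit_mse))
  invisible(x)
}

#' Evaluate the separable variogram and its covariance companion
#'
#' `sep_vgm_eval()` returns `sill * (gs + gt - gs * gt)`; `sep_cov()` returns
#' `sill - gamma_sep`, the covariance used to build kriging systems.
#'
#' @param model A [sep_vgm()] object.
#' @param h Spatial lags (km), non-negative.
#' @param tau Temporal lags (months), non-negative; recycled against `h`.
#' @return Numeric, same shape as `h` after recycling.
#' @examples
#' m <- sep_vgm(2, vgm_model("exponential", 100), vgm_model("exponential", 3))
#' sep_vgm_eval(m, 0, 0)
#' @export
sep_vgm_eval <- function(model, h, tau) {
  if (any(h < 0) || any(tau < 0)) abort("Lags must be non-negative.")
  gs <- vgm_eval(model$spatial, h)
  gt <- vgm_eval(model$temporal, tau)
  model$sill * (gs + gt - gs * gt)
}

#' @rdname sep_vgm_eval
#' @export
sep_cov <- function(model, h, tau) {
  model$sill - sep_vgm_eval(model, h, tau)
}

#' Empirical spatio-temporal variogram of station residuals
#'
#' Computes binned semivariances
#' `gamma(h_bin, tau) = mean of (z(s_i, t) - z(s_j, t + tau))^2 / 2` over all
#' station pairs whose separation falls in the spatial bin, at each integer
#' temporal lag. The (0, 0) cell (a station against itself at lag zero) is
#' excluded. Empty bins are reported as missing, not zero.
#'
#' @param data Long residual series tibble (`station_id`, `time_index`,
#'   `value`), typically detrended log10 residuals.
#' @param stations Station tibble.
#' @param n_spatial_bins Number of equal-width spatial distance bins from 0 to
#'   the maximum station separation.
#' @param max_tlag Maximum temporal lag, months.
#' @param convention Distance convention.
#' @return An object of class `emp_st_variogram`: a tibble with columns
#'   `h` (bin midpoint), `tau`, `gamma`, `npairs` (products counted over time),
#'   carrying the bin edges as attribute `breaks`.
#' @export
empirical_st_variogram <- function(data, stations, n_spatial_bins = 12,
                                   max_tlag = 6,
                                   convention = c("great_circle_km", "euclidean_degrees")) {
  convention <- match.arg(convention)
  z <- series_matrix(data)
  stations <- dplyr::arrange(tibble::as_tibble(stations), .data$station_id)
  stopifnot(nrow(z) >= 2, ncol(z) >= 2)
  d <- pairwise_distance(stations, convention)
  n <- nrow(z); Tn <- ncol(z)
  max_tlag <- min(max_tlag, Tn - 1)
  breaks <- seq(0, max(d) * (1 + 1e-9), length.out = n_spatial_bins + 1)
  bin_of <- matrix(findInterval(d, breaks, rightmost.closed = TRUE), n, n)
  diag(bin_of) <- 0L  # pure temporal lags: h exactly 0
  rows <- list()
  for (tau in 0:max_tlag) {
    a <- z[, seq_len(Tn - tau), drop = FALSE]
    b <- z[, seq_len(Tn - tau) + tau, drop = FALSE]
    nt <- ncol(a)
    # sq[i, j] = mean over t of (z_i(t) - z_j(t + tau))^2
    cross <- tcrossprod(a, b) / nt
    sq <- outer(rowMeans(a^2), rep(1, n)) + outer(rep(1, n), rowMeans(b^2)) - 2 * cross
    if (tau == 0) {
      keep <- upper.tri(sq)  # (i, j) with i < j; (0,0) self-pairs excluded
    } else {
      keep <- matrix(TRUE, n, n)  # ordered pairs, includes i = j (pure temporal)
    }
    df <- tibble::tibble(
      bin = bin_of[keep],
      tau = tau,
      sq = sq[keep],
      w = nt
    )
    # distance bin 0 means d = 0 exactly (i = j), map to first bin midpoint 0
    rows[[length(rows) + 1]] <- df
  }
  all_rows <- dplyr::bind_rows(rows)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  emp <- all_rows |>
    dplyr::group_by(.data$bin, .data$tau) |>
    dplyr::summarise(
      gamma = sum(.data$sq * .data$w) / (2 * sum(.data$w)),
      npairs = sum(.data$w),
      .groups = "drop"
    ) |>
    dplyr::mutate(h = ifelse(.data$bin == 0, 0, mids[pmax(.data$bin, 1)])) |>
    dplyr::select("h", "tau", "gamma", "npairs") |>
    dplyr::arrange(.data$tau, .data$h)
  structure(
    emp,
    breaks = breaks,
    convention = convention,
    class = c("emp_st_variogram", class(emp))
  )
}

#' Fit a separable variogram to an empirical surface by weighted least squares
#'
#' Minimizes the pair-count-weighted squared error between the empirical
#' semivariances and the separable model, over (sill, spatial range, temporal
#' range, both nugget fractions), using bounded L-BFGS-B from a small grid of
#' documented starts (ranges at 1/4, 1/2 and 1 of the maximum lag in each
#' dimension). Deterministic given the data.
#'
#' @param emp An [empirical_st_variogram()] result.
#' @param spatial_family,temporal_family Marginal families.
#' @param nu_s,nu_t Matern smoothness, fixed (not fitted) by default.
#' @param weights `"npairs"` (default) or `"equal"`.
#' @return A [sep_vgm()] object with extra fields `fit_mse` (weighted mean
#'   squared fit error) and `convergence`.
#' @export
fit_separable <- function(emp, spatial_family = "exponential",
                          temporal_family = "exponential",
                          nu_s = 1.5, nu_t = 1.5,
                          weights = c("npairs", "equal")) {
  weights <- match.arg(weights)
  emp <- emp[is.finite(emp$gamma), , drop = FALSE]
  if (nrow(emp) < 4) abort("Need at least 4 non-empty variogram bins to fit.")
  w <- if (weights == "npairs") emp$npairs else rep(1, nrow(emp))
  w <- w / sum(w)
  max_h <- max(emp$h); max_tau <- max(max(emp$tau), 1)
  sill0 <- max(max(emp$gamma), .Machine$double.eps)
  # optimize in normalized units (semivariances / sill0, ranges / max lag) so
  # the objective and gradients are O(1) regardless of the data scale
  gamma_hat <- emp$gamma / sill0

  par_model <- function(par) {
    sep_vgm(
      sill = par[["sill"]] * sill0,
      spatial = vgm_model(spatial_family, range = par[["rs"]] * max_h,
                          nugget = par[["ns"]], nu = nu_s),
      temporal = vgm_model(temporal_family, range = par[["rt"]] * max_tau,
                           nugget = par[["nt"]], nu = nu_t)
    )
  }
  obj <- function(par) {
    m <- par_model(par)
    sum(w * (sep_vgm_eval(m, emp$h, emp$tau) / sill0 - gamma_hat)^2)
  }
  lower <- c(sill = 1e-6, rs = 1e-3, rt = 1e-3, ns = 0, nt = 0)
  upper <- c(sill = 10, rs = 10, rt = 10, ns = 0.95, nt = 0.95)
  best <- NULL
  for (fr in c(0.25, 0.5, 1)) {
    start <- c(sill = 1, rs = fr, rt = fr, ns = 0.05, nt = 0.05)
    fit <- tryCatch(
      optim(start, obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500)),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) abort("Separable variogram fit failed to converge from all starts.")
  model <- par_model(best$par)
  model$fit_mse <- best$value * sill0^2
  model$convergence <- best$convergence
  model
}

#' @exportS3Method generics::tidy
tidy.separable_variogram <- function(x, ...) {
  tibble::tibble(
    term = c("sill", "spatial_range", "spatial_nugget", "temporal_range",
             "temporal_nugget"),
    estimate = c(x$sill, x$spatial$range, x$spatial$nugget, x$temporal$range,
                 x$temporal$nugget)
  )
}

#' @exportS3Method generics::glance
glance.separable_variogram <- function(x, ...) {
  tibble::tibble(
    spatial_family = x$spatial$family,
    temporal_family = x$temporal$family,
    sill = x$sill,
    fit_mse = x$fit_mse %||% NA_real_
  )
}
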