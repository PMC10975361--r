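# Cross-method comparison: Friedman omnibus test on per-station metric ranks
# with a Nemenyi post-hoc (studentized-range approximation), and spatial
# autocorrelation diagnostics (Moran's I, Geary's C) on per-station LOOCV
# residuals with permutation p-values.

#' Friedman test with Nemenyi post-hoc over methods
#'
#' Blocks are stations, treatments are methods, responses are a per-station
#' error metric. Runs the Friedman rank test, pairwise Nemenyi comparisons
#' via the studentized-range approximation, and reports the mean-error
#' reduction (percent) of each column method relative to each row method.
#'
#' @param metric_matrix Numeric matrix or data frame, stations x methods,
#'   with method names as column names.
#' @return An object of class `method_comparison`: `friedman` (statistic, df,
#'   p), `mean_ranks`, `nemenyi_p` (symmetric matrix, unit diagonal),
#'   `reduction_pct` (`reduction_pct[a, b]` = percent reduction of method b's
#'   mean metric relative to method a's).
#' @export
friedman_nemenyi <- function(metric_matrix) {
  m <- as.matrix(metric_matrix)
  if (is.null(colnames(m))) colnames(m) <- paste0("method", seq_len(ncol(m)))
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) abort("Need at least 2 stations and 2 methods.")
  ranks <- t(apply(m, 1, rank))
  rbar <- colMeans(ranks)
  if (all(apply(m, 1, function(r) length(unique(r)) == 1))) {
    stat <- 0; p <- 1; df <- k - 1
  } else {
    ft <- friedman.test(m)
    stat <- unname(ft$statistic); p <- ft$p.value; df <- unname(ft$parameter)
  }
  se <- sqrt(k * (k + 1) / (12 * n))
  q <- abs(outer(rbar, rbar, "-")) / se
  nem <- 1 - ptukey(q, nmeans = k, df = Inf)
  diag(nem) <- 1
  means <- colMeans(m)
  red <- 100 * outer(means, means, function(a, b) (a - b) / a)
  structure(
    list(
      friedman = tibble::tibble(statistic = stat, df = df, p = p),
      mean_ranks = rbar,
      nemenyi_p = nem,
      reduction_pct = red,
      metric_matrix = m
    ),
    class = "method_comparison"
  )
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("Friedman test: chi2 = %.4g (df %d), p = %.4g\n",
              x$friedman$statistic, x$friedman$df, x$friedman$p))
  cat("Mean ranks:\n"); print(round(x$mean_ranks, 3))
  cat("Nemenyi pairwise p-values:\n"); print(round(x$nemenyi_p, 4))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.method_comparison <- function(x, ...) x$friedman

#' Spatial weight matrix for station autocorrelation tests
#'
#' @param stations Station tibble.
#' @param style `"idw"`: row-standardized inverse-distance weights;
#'   `"knn"`: row-standardized binary k-nearest-neighbour weights.
#' @param k Number of neighbours for `style = "knn"`.
#' @param convention Distance convention.
#' @return An `n x n` weight matrix with zero diagonal and unit row sums.
#' @export
spatial_weights <- function(stations, style = c("idw", "knn"), k = 4,
                            convention = c("great_circle_km", "euclidean_degrees")) {
  style <- match.arg(style)
  convention <- match.arg(convention)
  d <- pairwise_distance(stations, convention)
  n <- nrow(d)
  w <- matrix(0, n, n, dimnames = dimnames(d))
  if (style == "idw") {
    w <- 1 / d
    diag(w) <- 0
    w[!is.finite(w)] <- 0
  } else {
    for (i in seq_len(n)) {
      nb <- order(d[i, -i])[seq_len(min(k, n - 1))]
      w[i, setdiff(seq_len(n), i)[nb]] <- 1
    }
  }
  sums <- rowSums(w)
  w / ifelse(sums > 0, sums, 1)
}

#' Moran's I with permutation test
#'
#' `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with `z` the centred
#' values and `S0` the total weight. Under the permutation null,
#' `E[I] = -1 / (n - 1)`.
#'
#' @param values Per-station values (non-constant).
#' @param weights Spatial weight matrix with zero diagonal (e.g.
#'   [spatial_weights()]).
#' @param n_perm Number of permutations for the p-value.
#' @param seed Seed for the permutations.
#' @return Tibble with `statistic`, `expectation`, `p` (two-sided permutation
#'   p-value).
#' @export
morans_i <- function(values, weights, n_perm = 999, seed = 1) {
  autocorr_stat(values, weights, n_perm, seed, stat = "moran")
}

#' Geary's C with permutation test
#'
#' `C = ((n - 1) / (2 S0)) * sum_ij w_ij (x_i - x_j)^2 / sum_i z_i^2`; values
#' below 1 indicate positive spatial autocorrelation. Null expectation 1.
#'
#' @inheritParams morans_i
#' @return Tibble with `statistic`, `expectation`, `p`.
#' @export
gearys_c <- function(values, weights, n_perm = 999, seed = 1) {
  autocorr_stat(values, weights, n_perm, seed, stat = "geary")
}

autocorr_stat <- function(values, weights, n_perm, seed, stat) {
  n <- length(values)
  w <- as.matrix(weights)
  if (any(diag(w) != 0)) abort("Weight matrix must have a zero diagonal.")
  if (sd(values) == 0) abort("Autocorrelation undefined for constant values.")
  s0 <- sum(w)
  observed <- compute_autocorr(values, w, s0, stat)
  expectation <- if (stat == "moran") -1 / (n - 1) else 1
  p <- NA_real_
  if (n_perm > 0) {
    sims <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        compute_autocorr(sample(values), w, s0, stat)
      }, numeric(1))
    })
    extreme <- sum(abs(sims - mean(sims)) >= abs(observed - mean(sims)))
    p <- (extreme + 1) / (n_perm + 1)
  }
  tibble::tibble(statistic = observed, expectation = expectation, p = p)
}

compute_autocorr <- function(x, w, s0, stat) {
  z <- x - mean(x)
  if (stat == "moran") {
    (length(x) / s0) * sum(w * outer(z, z)) / sum(z^2)
  } else {
    ((length(x) - 1) / (2 * s0)) * sum(w * outer(x, x, function(a, b) (a - b)^2)) / sum(z^2)
  }
}

#' Run all interpolation methods and compare them
#'
#' Runs station-omission LOOCV for the selected methods on one series,
#' assembles per-station metric tables, compares the methods with Friedman
#' and Nemenyi tests on each error metric, and tests the per-station mean
#' LOOCV residuals of each method for spatial autocorrelation (Moran's I,
#' Geary's C). Deterministic given `seed`.
#'
#' @param data Long series tibble.
#' @param stations Station tibble.
#' @param methods Subset of `c("idw", "bss", "stk")`.
#' @param seed Seed for the permutation tests.
#' @param idw_beta `"auto"` (LOOCV selection over `idw_betas`) or a number.
#' @param idw_betas Candidate powers when `idw_beta = "auto"`.
#' @param k_nearest,offset Buffer options for BSS, see [build_buffer()].
#' @param stk_options List of extra arguments passed to [stk_loocv()].
#' @param n_perm Permutations for the autocorrelation tests.
#' @param convention Distance convention.
#' @return An object of class `st_benchmark`: `folds` (per-method LOOCV
#'   predictions), `metrics` (per-method per-station tables), `aggregates`,
#'   `comparisons` (one `method_comparison` per error metric), `autocorr`
#'   (per-method Moran/Geary tibble), `idw_beta`, and `stk` (the full
#'   [stk_loocv()] object when run).
#' @export
benchmark_methods <- function(data, stations, methods = c("idw", "bss", "stk"),
                              seed = 1, idw_beta = "auto", idw_betas = 1:10,
                              k_nearest = 3, offset = NULL,
                              stk_options = list(), n_perm = 999,
                              convention = c("great_circle_km", "euclidean_degrees")) {
  convention <- match.arg(convention)
  methods <- match.arg(methods, several.ok = TRUE)
  folds <- list()
  extras <- list()
  if ("idw" %in% methods) {
    if (identical(idw_beta, "auto")) {
      opt <- idw_optimize(data, stations, betas = idw_betas, convention = convention)
      folds$idw <- opt$folds
      extras$idw_beta <- opt$beta
      extras$idw_scores <- opt$scores
    } else {
      folds$idw <- idw_loocv(data, stations, beta = idw_beta, convention = convention)
      extras$idw_beta <- idw_beta
    }
  }
  if ("bss" %in% methods) {
    folds$bss <- bss_loocv(data, stations, k_nearest = k_nearest, offset = offset,
                           convention = convention)
  }
  if ("stk" %in% methods) {
    stk <- do.call(stk_loocv, c(list(data = data, stations = stations,
                                     convention = convention), stk_options))
    folds$stk <- stk$folds[, c("station_id", "time_index", "observed", "predicted")]
    extras$stk <- stk
  }
  metrics <- lapply(folds, station_metrics)
  aggregates <- lapply(metrics, aggregate_metrics)
  comparisons <- NULL
  if (length(folds) >= 2) {
    comparisons <- lapply(c(mae = "mae", rmse = "rmse", mape = "mape"), function(metric) {
      mm <- sapply(metrics, function(tab) tab[[metric]])
      rownames(mm) <- metrics[[1]]$station_id
      friedman_nemenyi(mm)
    })
  }
  w <- spatial_weights(stations, convention = convention)
  autocorr <- purrr::imap_dfr(folds, function(f, nm) {
    res <- f |>
      dplyr::group_by(.data$station_id) |>
      dplyr::summarise(resid = mean(.data$observed - .data$predicted), .groups = "drop")
    dplyr::bind_cols(
      tibble::tibble(method = nm),
      dplyr::rename_with(morans_i(res$resid, w, n_perm, seed), ~ paste0("moran_", .x)),
      dplyr::rename_with(gearys_c(res$resid, w, n_perm, seed), ~ paste0("geary_", .x))
    )
  })
  structure(
    c(list(folds = folds, metrics = metrics, aggregates = aggregates,
           comparisons = comparisons, autocorr = autocorr, seed = seed,
           methods = methods), extras),
    class = "st_benchmark"
  )
}

#' @export
print.st_benchmark <- function(x, ...) {
  cat("Interpolation benchmark:", paste(x$methods, collapse = ", "), "\n")
  for (nm in names(x$aggregates)) {
    avg <- x$aggregates[[nm]][x$aggregates[[nm]]$stat == "average", ]
    cat(sprintf("  %-4s mean MAE %.4g, RMSE %.4g, MAPE %.4g%%\n",
                nm, avg$mae, avg$rmse, avg$mape))
  }
  if (!is.null(x$comparisons)) {
    cat(sprintf("  Friedman p (MAE): %.4g\n", x$comparisons$mae$friedman$p))
  }
  invisible(x)
}
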