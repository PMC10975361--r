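# Piecewise-bicubic Hermite interpolation on a complete rectangular grid.
# Node derivatives are estimated by centered finite differences (one-sided at
# the boundary); sharing them across cells makes the surface C1. Within each
# cell the surface is the bicubic polynomial sum(a_ij x^i y^j); the monomial
# coefficients are recoverable from the Hermite data by a fixed linear map,
# see bicubic_cell_coefficients().

# Hermite basis coefficient matrix: column k holds the monomial coefficients
# (1, t, t^2, t^3) of basis function k = (value at 0, value at 1, slope at 0,
# slope at 1).
HERMITE_M <- matrix(c(
  1, 0, -3, 2,
  0, 0, 3, -2,
  0, 1, -2, 1,
  0, 0, -1, 1
), 4, 4)

# Centered finite differences along the first axis of z over coords x
fd_gradient <- function(x, z) {
  n <- length(x)
  g <- z
  if (n == 1) {
    g[] <- 0
    return(g)
  }
  g[1, ] <- (z[2, ] - z[1, ]) / (x[2] - x[1])
  g[n, ] <- (z[n, ] - z[n - 1, ]) / (x[n] - x[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    g[i, ] <- (z[i + 1, ] - z[i - 1, ]) / (x[i + 1] - x[i - 1])
  }
  g
}

#' Bicubic Hermite interpolation on a complete rectangular grid
#'
#' Builds a C1 piecewise-bicubic surface through `z[i, j] = f(x[i], y[j])`,
#' exact at the nodes, with node derivatives estimated by centered finite
#' differences (one-sided at the boundary), and evaluates it at query points.
#'
#' @param x,y Strictly increasing grid coordinate vectors.
#' @param z Value matrix, `length(x)` rows by `length(y)` columns.
#' @param xout,yout Query coordinates (equal-length vectors, paired).
#' @return Numeric vector of interpolated values.
#' @export
interp_grid_bicubic <- function(x, y, z, xout, yout) {
  stopifnot(length(x) >= 2, length(y) >= 2, all(diff(x) > 0), all(diff(y) > 0))
  if (!is.matrix(z) || nrow(z) != length(x) || ncol(z) != length(y)) {
    abort("`z` must be a length(x) by length(y) matrix.")
  }
  if (length(xout) != length(yout)) abort("`xout` and `yout` must have equal length.")
  eps <- 1e-9 * max(diff(range(x)), diff(range(y)))
  bad <- xout < min(x) - eps | xout > max(x) + eps |
    yout < min(y) - eps | yout > max(y) + eps
  if (any(bad)) {
    abort(sprintf(
      "Query point(s) outside the grid: %s",
      paste(sprintf("(%.4g, %.4g)", xout[bad], yout[bad]), collapse = ", ")
    ))
  }
  zx <- fd_gradient(x, z)
  zy <- t(fd_gradient(y, t(z)))
  zxy <- t(fd_gradient(y, t(zx)))
  ix <- pmin(pmax(findInterval(xout, x), 1), length(x) - 1)
  iy <- pmin(pmax(findInterval(yout, y), 1), length(y) - 1)
  out <- numeric(length(xout))
  for (q in seq_along(xout)) {
    i <- ix[q]; j <- iy[q]
    hx <- x[i + 1] - x[i]; hy <- y[j + 1] - y[j]
    u <- (xout[q] - x[i]) / hx
    v <- (yout[q] - y[j]) / hy
    G <- hermite_cell_matrix(z, zx, zy, zxy, i, j, hx, hy)
    uu <- c(1, u, u^2, u^3)
    vv <- c(1, v, v^2, v^3)
    out[q] <- drop(uu %*% (HERMITE_M %*% G %*% t(HERMITE_M)) %*% vv)
  }
  out
}

hermite_cell_matrix <- function(z, zx, zy, zxy, i, j, hx, hy) {
  ii <- c(i, i + 1); jj <- c(j, j + 1)
  rbind(
    cbind(z[ii, jj], zy[ii, jj] * hy),
    cbind(zx[ii, jj] * hx, zxy[ii, jj] * hx * hy)
  )
}

#' Monomial coefficients of one bicubic cell
#'
#' Returns the 4 x 4 matrix `a` such that the surface restricted to grid cell
#' `(i, j)` equals `sum_{p,q} a[p+1, q+1] u^p v^q` in the cell-local unit
#' coordinates `u = (x - x[i]) / (x[i+1] - x[i])`, `v = (y - y[j]) / (y[j+1] -
#' y[j])`. This is the explicit linear map from the Hermite data (values and
#' finite-difference derivatives at the four cell corners) to the polynomial
#' coefficients.
#'
#' @inheritParams interp_grid_bicubic
#' @param i,j Cell indices (1-based, `i < length(x)`, `j < length(y)`).
#' @return A 4 x 4 numeric matrix of monomial coefficients.
#' @export
bicubic_cell_coefficients <- function(x, y, z, i, j) {
  stopifnot(i >= 1, i < length(x), j >= 1, j < length(y))
  zx <- fd_gradient(x, z)
  zy <- t(fd_gradient(y, t(z)))
  zxy <- t(fd_gradient(y, t(zx)))
  hx <- x[i + 1] - x[i]; hy <- y[j + 1] - y[j]
  G <- hermite_cell_matrix(z, zx, zy, zxy, i, j, hx, hy)
  HERMITE_M %*% G %*% t(HERMITE_M)
}
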