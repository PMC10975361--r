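# Clough-Tocher C1 piecewise-cubic interpolation of scattered data on a
# Delaunay triangulation. Each macro-triangle is split at its centroid into
# three cubic Bezier patches. The centroid split makes the continuity
# conditions explicit: with vertices V1 V2 V3, centroid C, patch t on
# (Va, Vb, C) and known ordinates
#   b300 = f(Va),  b210 = f(Va) + g(Va).(Vb - Va)/3,  (outer edge)
#   b201 = f(Va) + g(Va).(C - Va)/3,                  (toward centre)
# the interior ordinate b111 of each patch follows from requiring the
# cross-edge (normal) derivative to vary linearly along the outer edge, the
# second-ring ordinate on internal edge Va-C is (u_t + u_t' + b201(Va)) / 3
# (u = b111 of the two patches meeting there), and the centre ordinate is the
# mean of the three second-ring ordinates. Vertex gradients are estimated by
# local least-squares fits over triangulation neighbours, which gives the
# interpolant linear precision.

#' Build a Clough-Tocher interpolant over scattered points
#'
#' Triangulates the points (Delaunay), estimates vertex gradients by local
#' least squares over neighbouring points, and returns a reusable interpolant
#' object. The resulting surface is C1, exact at the data points, and
#' reproduces planes exactly.
#'
#' @param x,y Point coordinates (no duplicates).
#' @return An object of class `ct_interp` holding the triangulation and the
#'   linear gradient-estimation operator; evaluate with [ct_eval()].
#' @export
ct_build <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 4) abort("Clough-Tocher interpolation needs at least 4 points.")
  if (anyDuplicated(cbind(x, y))) abort("Duplicate point locations.")
  dd <- deldir::deldir(x, y, suppressMsge = TRUE)
  tri <- deldir::triMat(dd)
  # neighbour sets from triangulation edges
  nbr <- vector("list", n)
  for (r in seq_len(nrow(tri))) {
    v <- tri[r, ]
    nbr[[v[1]]] <- c(nbr[[v[1]]], v[2], v[3])
    nbr[[v[2]]] <- c(nbr[[v[2]]], v[1], v[3])
    nbr[[v[3]]] <- c(nbr[[v[3]]], v[1], v[2])
  }
  nbr <- lapply(nbr, unique)
  # second ring where the first is too small for a stable fit
  for (i in seq_len(n)) {
    if (length(nbr[[i]]) < 5) {
      nbr[[i]] <- setdiff(unique(c(nbr[[i]], unlist(nbr[nbr[[i]]]))), i)
    }
  }
  # gradient operator: row pairs (gx_i, gy_i) as linear combinations of z
  scale <- max(diff(range(x)), diff(range(y)))
  Gx <- matrix(0, n, n)
  Gy <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- nbr[[i]]
    dx <- (x[j] - x[i]) / scale
    dy <- (y[j] - y[i]) / scale
    X <- if (length(j) >= 5) {
      cbind(dx, dy, dx^2, dx * dy, dy^2)
    } else {
      cbind(dx, dy)
    }
    # least-squares fit of z_j - z_i ~ X; gradient rows of the pseudo-inverse
    P <- tryCatch(solve(crossprod(X), t(X)), error = function(e) {
      XtX <- crossprod(X)
      solve(XtX + 1e-10 * max(diag(XtX)) * diag(ncol(X)), t(X))
    })
    Gx[i, j] <- P[1, ] / scale
    Gx[i, i] <- -sum(P[1, ]) / scale
    Gy[i, j] <- P[2, ] / scale
    Gy[i, i] <- -sum(P[2, ]) / scale
  }
  # per-triangle barycentric coefficients for vectorized point location
  x1 <- x[tri[, 1]]; y1 <- y[tri[, 1]]
  x2 <- x[tri[, 2]]; y2 <- y[tri[, 2]]
  x3 <- x[tri[, 3]]; y3 <- y[tri[, 3]]
  structure(
    list(x = x, y = y, tri = tri, Gx = Gx, Gy = Gy,
         a1 = y2 - y3, b1 = x3 - x2, a2 = y3 - y1, b2 = x1 - x3,
         x3r = x3, y3r = y3,
         det = (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)),
    class = "ct_interp"
  )
}

# Index of the triangle containing each query point (NA when outside hull)
ct_locate <- function(obj, xout, yout, tol = 1e-9) {
  vapply(seq_along(xout), function(q) {
    l1 <- (obj$a1 * (xout[q] - obj$x3r) + obj$b1 * (yout[q] - obj$y3r)) / obj$det
    l2 <- (obj$a2 * (xout[q] - obj$x3r) + obj$b2 * (yout[q] - obj$y3r)) / obj$det
    hit <- which(l1 >= -tol & l2 >= -tol & (1 - l1 - l2) >= -tol)
    if (length(hit) == 0) NA_integer_ else hit[1]
  }, integer(1))
}

# Barycentric coordinates of (px, py) in triangle (x1..3, y1..3)
barycentric <- function(px, py, x1, y1, x2, y2, x3, y3) {
  det <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
  l1 <- ((y2 - y3) * (px - x3) + (x3 - x2) * (py - y3)) / det
  l2 <- ((y3 - y1) * (px - x3) + (x1 - x3) * (py - y3)) / det
  cbind(l1, l2, 1 - l1 - l2)
}

#' Evaluate a Clough-Tocher interpolant
#'
#' @param obj A [ct_build()] object.
#' @param z Data values at the build points.
#' @param xout,yout Query coordinates. Queries outside the convex hull of the
#'   build points are an error listing the offending points.
#' @param cells Optional precomputed triangle indices from `ct_locate()`
#'   (reused across evaluations at fixed locations).
#' @return Numeric vector of interpolated values.
#' @export
ct_eval <- function(obj, z, xout, yout, cells = NULL) {
  stopifnot(length(z) == length(obj$x), length(xout) == length(yout))
  gx <- drop(obj$Gx %*% z)
  gy <- drop(obj$Gy %*% z)
  if (is.null(cells)) cells <- ct_locate(obj, xout, yout)
  if (anyNA(cells)) {
    bad <- which(is.na(cells))
    abort(sprintf(
      "Query point(s) outside the convex hull of the data: %s",
      paste(sprintf("(%.4g, %.4g)", xout[bad], yout[bad]), collapse = ", ")
    ))
  }
  out <- numeric(length(xout))
  for (q in seq_along(xout)) {
    v <- obj$tri[cells[q], ]
    out[q] <- ct_eval_triangle(
      obj$x[v], obj$y[v], z[v], gx[v], gy[v], xout[q], yout[q]
    )
  }
  out
}

# One macro-triangle CT evaluation: vertices (vx, vy), values f, gradients
# (gx, gy), query (px, py).
ct_eval_triangle <- function(vx, vy, f, gx, gy, px, py) {
  cx <- mean(vx); cy <- mean(vy)
  # known ordinates
  e_out <- function(a, b) f[a] + (gx[a] * (vx[b] - vx[a]) + gy[a] * (vy[b] - vy[a])) / 3
  q_in <- function(a) f[a] + (gx[a] * (cx - vx[a]) + gy[a] * (cy - vy[a])) / 3
  # patches: t = 1 on (V1, V2, C), 2 on (V2, V3, C), 3 on (V3, V1, C)
  pa <- c(1, 2, 3)
  pb <- c(2, 3, 1)
  u <- numeric(3)
  for (t in 1:3) {
    a <- pa[t]; b <- pb[t]
    b300 <- f[a]; b030 <- f[b]
    b210 <- e_out(a, b); b120 <- e_out(b, a)
    b201 <- q_in(a); b021 <- q_in(b)
    # edge normal, and its barycentric direction (d1, d2, d3), sum 0
    ex <- vx[b] - vx[a]; ey <- vy[b] - vy[a]
    nx <- -ey; ny <- ex
    dl <- bary_direction(nx, ny, vx[a], vy[a], vx[b], vy[b], cx, cy)
    # reduced condition: middle Bernstein coefficient of the normal
    # derivative along the outer edge equals the mean of the end ones
    q0 <- dl[1] * b300 + dl[2] * b210 + dl[3] * b201
    q2 <- dl[1] * b120 + dl[2] * b030 + dl[3] * b021
    q1_known <- dl[1] * b210 + dl[2] * b120
    u[t] <- ((q0 + q2) / 2 - q1_known) / dl[3]
  }
  # second-ring ordinates on internal edges Va-C: patches meeting at Va are
  # patch t (with A1 = Va) and patch t-1 (with A2 = Va)
  w <- numeric(3)
  for (a in 1:3) {
    t_lead <- a               # patch with A1 = Va
    t_trail <- ((a - 2) %% 3) + 1  # patch with A2 = Va
    w[a] <- (u[t_lead] + u[t_trail] + q_in(a)) / 3
  }
  c0 <- mean(w)
  # locate subpatch and evaluate its cubic Bernstein form
  lam <- drop(barycentric(px, py, vx[1], vy[1], vx[2], vy[2], vx[3], vy[3]))
  lam <- pmax(lam, 0); lam <- lam / sum(lam)
  t <- which.min(lam)        # smallest macro barycentric -> opposite patch
  t <- c(2, 3, 1)[t]         # lam1 smallest -> patch (V2, V3, C), etc.
  a <- pa[t]; b <- pb[t]
  sub <- barycentric(px, py, vx[a], vy[a], vx[b], vy[b], cx, cy)
  l1 <- sub[1]; l2 <- sub[2]; l3 <- sub[3]
  ords <- c(
    `300` = f[a], `030` = f[b], `003` = c0,
    `210` = e_out(a, b), `120` = e_out(b, a),
    `201` = q_in(a), `021` = q_in(b),
    `102` = w[a], `012` = w[b],
    `111` = u[t]
  )
  idx <- rbind(
    c(3, 0, 0), c(0, 3, 0), c(0, 0, 3),
    c(2, 1, 0), c(1, 2, 0),
    c(2, 0, 1), c(0, 2, 1),
    c(1, 0, 2), c(0, 1, 2),
    c(1, 1, 1)
  )
  coef <- factorial(3) / (factorial(idx[, 1]) * factorial(idx[, 2]) * factorial(idx[, 3]))
  sum(ords * coef * l1^idx[, 1] * l2^idx[, 2] * l3^idx[, 3])
}

# Barycentric components (d1, d2, d3), d1 + d2 + d3 = 0, of direction (dx, dy)
# with respect to triangle (x1..3, y1..3)
bary_direction <- function(dx, dy, x1, y1, x2, y2, x3, y3) {
  b1 <- barycentric(dx, dy, x1, y1, x2, y2, x3, y3)
  b0 <- barycentric(0, 0, x1, y1, x2, y2, x3, y3)
  drop(b1 - b0)
}

#' Clough-Tocher interpolation of scattered data
#'
#' One-shot convenience wrapper around [ct_build()] and [ct_eval()]: a C1
#' piecewise-cubic interpolant on the Delaunay triangulation of the points,
#' exact at the data points, with linear precision. Queries outside the convex
#' hull are an error (the condition that boundary buffering is designed to
#' remove).
#'
#' @param points Tibble with columns `x`, `y`, `value` (any planar
#'   coordinates; lon/lat used directly).
#' @param xout,yout Query coordinates.
#' @return Numeric vector of interpolated values.
#' @export
interp_scattered_cubic <- function(points, xout, yout) {
  check_cols(points, c("x", "y", "value"), "points")
  obj <- ct_build(points$x, points$y)
  ct_eval(obj, points$value, xout, yout)
}
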