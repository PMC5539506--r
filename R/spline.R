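# Cubic smoothing spline by the Reinsch / Green-Silverman band construction.
#
# Minimizes  sum_i (y_i - f(x_i))^2 + lambda * integral f''(x)^2 dx
# over natural cubic splines with knots at the data sites. Note the penalty
# convention: lambda multiplies the raw curvature integral and the error term
# is NOT divided by n -- this matches the energy as written for the pH-color
# curves and differs from stats::smooth.spline's internal scaling, which is
# why the solver is implemented here (the fit is 15 points; cost is nil).

#' Fit a cubic smoothing spline
#'
#' Solves `(I + lambda K) f = y` with `K = Q R^-1 Q^T` the natural-spline
#' roughness matrix (Green & Silverman band construction). `lambda = 0`
#' returns the interpolating natural cubic spline; `lambda -> Inf` tends to
#' the least-squares straight line.
#'
#' @param x Strictly increasing knot locations (length n >= 3).
#' @param y Responses at the knots.
#' @param lambda Smoothing weight, >= 0, multiplying the curvature integral.
#' @return Object of class `smoothing_spline` with fitted knot values and
#'   second derivatives, supporting [smoothing_spline_eval()].
#' @export
smoothing_spline_fit <- function(x, y, lambda) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            length(x) >= 3L, all(is.finite(x)), all(is.finite(y)),
            all(diff(x) > 0))
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda < 0)
    stop("lambda must be a finite non-negative scalar")
  n <- length(x)
  h <- diff(x)
  # Q: n x (n-2), R: (n-2) x (n-2) tridiagonal (interior knots 2..n-1)
  Q <- matrix(0, n, n - 2)
  R <- matrix(0, n - 2, n - 2)
  for (i in seq_len(n - 2)) {
    Q[i, i]     <- 1 / h[i]
    Q[i + 1, i] <- -1 / h[i] - 1 / h[i + 1]
    Q[i + 2, i] <- 1 / h[i + 1]
    R[i, i] <- (h[i] + h[i + 1]) / 3
    if (i < n - 2) {
      R[i, i + 1] <- h[i + 1] / 6
      R[i + 1, i] <- h[i + 1] / 6
    }
  }
  K <- Q %*% solve(R, t(Q))
  # Solve (I + lambda K) f = y through the eigendecomposition of K, with
  # numerically-zero eigenvalues clamped to exactly zero: the direct solve
  # loses ~lambda * eps absolute accuracy for very large lambda, whereas the
  # clamped spectral form reproduces the lambda -> Inf limit (the least
  # squares straight line, K's null space) to machine precision.
  K <- (K + t(K)) / 2
  eg <- eigen(K, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  d[d < max(d) * 1e-12] <- 0
  f <- eg$vectors %*% (crossprod(eg$vectors, y) / (1 + lambda * d))
  gamma <- c(0, solve(R, t(Q) %*% f), 0)  # natural boundary: f'' = 0 at ends
  structure(list(x = x, y = y, f = as.numeric(f), gamma = as.numeric(gamma),
                 lambda = lambda),
            class = "smoothing_spline")
}

#' Evaluate a fitted smoothing spline
#'
#' Piecewise-cubic evaluation from knot values and second derivatives;
#' linear extrapolation (zero curvature) outside the knot range, as dictated
#' by the natural boundary conditions.
#'
#' @param fit A `smoothing_spline`.
#' @param xout Evaluation points.
#' @return Numeric vector of fitted values.
#' @export
smoothing_spline_eval <- function(fit, xout) {
  stopifnot(inherits(fit, "smoothing_spline"), all(is.finite(xout)))
  x <- fit$x; f <- fit$f; g <- fit$gamma
  n <- length(x)
  # end slopes for linear extrapolation
  h1 <- x[2] - x[1]; hn <- x[n] - x[n - 1]
  s1 <- (f[2] - f[1]) / h1 - h1 * (2 * g[1] + g[2]) / 6
  sn <- (f[n] - f[n - 1]) / hn + hn * (g[n - 1] + 2 * g[n]) / 6
  i <- findInterval(xout, x, rightmost.closed = TRUE)
  out <- numeric(length(xout))
  lo <- xout < x[1]; hi <- xout > x[n]
  out[lo] <- f[1] + s1 * (xout[lo] - x[1])
  out[hi] <- f[n] + sn * (xout[hi] - x[n])
  mid <- !lo & !hi
  if (any(mid)) {
    ii <- pmin(pmax(i[mid], 1L), n - 1L)
    h <- x[ii + 1] - x[ii]
    a <- (x[ii + 1] - xout[mid]) / h
    b <- (xout[mid] - x[ii]) / h
    out[mid] <- a * f[ii] + b * f[ii + 1] +
      ((a^3 - a) * g[ii] + (b^3 - b) * g[ii + 1]) * h^2 / 6
  }
  out
}

#' Decompose the fitted energy into error and smoothness terms
#'
#' Returns `E_error = sum (y - f)^2`, `E_smooth = integral f''^2`
#' (computed exactly from the piecewise-linear second derivative), and the
#' weighted total `E_error + lambda * E_smooth`.
#'
#' @param fit A `smoothing_spline`.
#' @return Named list with `error`, `smooth`, `total`.
#' @export
smoothing_spline_energy <- function(fit) {
  stopifnot(inherits(fit, "smoothing_spline"))
  h <- diff(fit$x)
  g <- fit$gamma
  n <- length(fit$x)
  # integral of (linear interpolant of g)^2 over each interval
  e_sm <- sum(h * (g[-n]^2 + g[-n] * g[-1] + g[-1]^2) / 3)
  e_err <- sum((fit$y - fit$f)^2)
  list(error = e_err, smooth = e_sm, total = e_err + fit$lambda * e_sm)
}
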