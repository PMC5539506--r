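# Shared fixtures and independent oracles. Everything is generated in code;
# the only file fixture is the bundled replicate table.

# one palette for the whole suite (deterministic)
test_palette <- default_palette(1L)

# chart captures straight from palette colors (no rendering) with an
# optional per-index color distortion applied to reference and target alike
make_color_captures <- function(pal = test_palette, distort = NULL) {
  lapply(0:14, function(P) {
    ref <- pal$reference_uv
    tgt <- strip_colors(pal, P)
    if (!is.null(distort)) {
      fp <- distort[[P + 1]]
      ref <- apply_color_model(fp, ref)
      tgt <- apply_color_model(fp, tgt)
    }
    chart_capture(P, ref, tgt)
  })
}

# random third-order model near the identity (current RNG)
random_poly_model <- function(scale = 0.05) {
  idm <- identity_color_model()
  poly_color_model(idm$a_u + runif(10, -scale, scale),
                   idm$a_v + runif(10, -scale, scale))
}

# true least-absolute-deviation minimum for a 3-parameter design by
# enumeration: an LAD optimum interpolates >= 3 of the n points, so the
# global minimum is found by solving every 3-subset exactly
lad_cost_oracle <- function(X, y) {
  stopifnot(ncol(X) == 3L)
  best <- Inf
  cmb <- utils::combn(nrow(X), 3)
  for (i in seq_len(ncol(cmb))) {
    S <- cmb[, i]
    a <- tryCatch(solve(X[S, ], y[S]), error = function(e) NULL)
    if (!is.null(a)) best <- min(best, sum(abs(y - X %*% a)))
  }
  best
}

# discretized variational oracle for the smoothing-spline energy: minimize
# sum_i (y_i - g(x_i))^2 + lambda * h * sum ((g_{j-1}-2g_j+g_{j+1})/h^2)^2
# over a fine grid by solving the sparse normal equations
spline_qp_oracle <- function(y, lambda, h = 0.005) {
  x <- seq(0, 14, by = h)
  m <- length(x)
  knots <- match(0:14, round(x, 10))
  S <- Matrix::sparseMatrix(i = seq_len(15), j = knots, x = 1,
                            dims = c(15, m))
  D <- Matrix::bandSparse(m - 2, m, k = 0:2,
                          diagonals = list(rep(1, m - 2), rep(-2, m - 2),
                                           rep(1, m - 2)))
  A <- Matrix::crossprod(S) + (lambda / h^3) * Matrix::crossprod(D)
  list(x = x, g = as.numeric(Matrix::solve(A, Matrix::crossprod(S, y))))
}

# blank light-gray canvas and simple shape painters for detector tests
blank_image <- function(h = 400, w = 400, gray = 205) {
  array(gray, c(h, w, 3))
}

paint_rect_outline <- function(img, x0, y0, x1, y1, lw = 3, value = 30) {
  img[(y0:(y0 + lw - 1)) + 1, (x0:x1) + 1, ] <- value
  img[((y1 - lw + 1):y1) + 1, (x0:x1) + 1, ] <- value
  img[(y0:y1) + 1, (x0:(x0 + lw - 1)) + 1, ] <- value
  img[(y0:y1) + 1, ((x1 - lw + 1):x1) + 1, ] <- value
  img
}

paint_polygon <- function(img, vx, vy, value = 30) {
  xr <- floor(min(vx)):ceiling(max(vx))
  yr <- floor(min(vy)):ceiling(max(vy))
  poly <- cbind(vx, vy)
  for (y in yr) for (x in xr) {
    if (phstrip:::.point_in_polygon(c(x, y), poly))
      img[y + 1, x + 1, ] <- value
  }
  img
}
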