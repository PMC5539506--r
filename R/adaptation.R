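# Robust chromatic adaptation: a third-order bivariate polynomial map from
# source (u', v') to destination (u', v'), one 10-coefficient regression per
# output channel (20 parameters total), fitted in the least-absolute-deviation
# sense by iteratively reweighted least squares (IRLS).

#' Third-order polynomial design row(s) for u'v' inputs
#'
#' Basis monomials in the fixed serialization order
#' \[u, v, 1, u^2, v^2, uv, u^3, v^3, u^2 v, u v^2\]; both output channels
#' share this basis.
#'
#' @param uv Length-2 vector `c(u, v)` or n x 2 matrix.
#' @return n x 10 design matrix.
#' @export
uv_design <- function(uv) {
  uv <- .as_uv_matrix(uv)
  u <- uv[, 1]; v <- uv[, 2]
  cbind(u, v, 1, u^2, v^2, u * v, u^3, v^3, u^2 * v, u * v^2)
}

#' Construct a polynomial color-converting model
#'
#' @param a_u,a_v Numeric length-10 coefficient vectors for the u' and v'
#'   output channels, ordered as in [uv_design()].
#' @return An object of class `poly_color_model`.
#' @export
poly_color_model <- function(a_u, a_v) {
  a_u <- as.numeric(a_u); a_v <- as.numeric(a_v)
  if (length(a_u) != 10L || length(a_v) != 10L)
    stop("a polynomial color model has exactly 10 + 10 = 20 coefficients")
  if (any(!is.finite(c(a_u, a_v)))) stop("model coefficients must be finite")
  structure(list(a_u = a_u, a_v = a_v), class = "poly_color_model")
}

#' The identity color-converting model
#'
#' The identity map is exactly representable in the polynomial family:
#' `a_u = (1,0,...,0)`, `a_v = (0,1,0,...,0)`.
#'
#' @return A `poly_color_model`.
#' @export
identity_color_model <- function() {
  poly_color_model(c(1, rep(0, 9)), c(0, 1, rep(0, 8)))
}

#' @export
print.poly_color_model <- function(x, ...) {
  cat("poly_color_model (third-order, 20 parameters)\n")
  cat("  a_u:", format(x$a_u, digits = 4), "\n")
  cat("  a_v:", format(x$a_v, digits = 4), "\n")
  invisible(x)
}

#' Apply a color-converting model to u'v' colors
#'
#' @param model A `poly_color_model`.
#' @param uv Length-2 vector or n x 2 matrix of source chromaticities.
#' @return n x 2 matrix of destination chromaticities.
#' @export
apply_color_model <- function(model, uv) {
  stopifnot(inherits(model, "poly_color_model"))
  X <- uv_design(uv)
  cbind(u = drop(X %*% model$a_u), v = drop(X %*% model$a_v))
}

#' @export
predict.poly_color_model <- function(object, uv, ...) apply_color_model(object, uv)

#' IRLS configuration for the L1 fit
#'
#' @param delta Lower clamp on the absolute residual when forming IRLS
#'   weights `w_i = 1 / max(delta, |r_i|)`; default 0.01.
#' @param iterations Number of reweighted solves; default 20. The iteration
#'   count is fixed (no convergence test) to keep fits reproducible across
#'   platforms; `tol` enables an optional early stop on the maximum
#'   coefficient change and is off (`0`) by default.
#' @param tol Optional early-stopping tolerance, default 0 (disabled).
#' @return An object of class `irls_config`.
#' @export
irls_config <- function(delta = 0.01, iterations = 20L, tol = 0) {
  stopifnot(is.numeric(delta), length(delta) == 1L, delta > 0,
            is.numeric(iterations), length(iterations) == 1L, iterations >= 1,
            is.numeric(tol), length(tol) == 1L, tol >= 0)
  structure(list(delta = delta, iterations = as.integer(iterations), tol = tol),
            class = "irls_config")
}

# One least-absolute-deviation regression y ~ X by IRLS.
# Weighted solves use a QR least-squares solve of sqrt(w)-scaled rows, which
# satisfies the same normal-equation fixed point as the textbook
# (X'WX)^{-1}X'Wy update but is numerically stable.
.irls_lad <- function(X, y, cfg) {
  w <- rep(1, nrow(X))
  a <- NULL
  for (t in seq_len(cfg$iterations)) {
    sw <- sqrt(w)
    fit <- qr(X * sw)
    if (fit$rank < ncol(X))
      stop("design matrix is rank deficient (rank ", fit$rank, " < ",
           ncol(X), "); reference colors do not span the polynomial basis")
    a_new <- qr.coef(fit, y * sw)
    if (!is.null(a) && cfg$tol > 0 && max(abs(a_new - a)) < cfg$tol) {
      a <- a_new
      break
    }
    a <- a_new
    r <- y - drop(X %*% a)
    w <- 1 / pmax(cfg$delta, abs(r))
  }
  a
}

#' Fit the color-converting model between two u'v' color sets
#'
#' For each output channel independently, minimizes the sum of absolute
#' residuals `sum_i |y_i - X_i a|` over the 10 polynomial coefficients by
#' iteratively reweighted least squares: `w_i(0) = 1`,
#' `a(t+1) = argmin_a sum_i w_i(t) (y_i - X_i a)^2`,
#' `w_i(t) = 1 / max(delta, |y_i - X_i a(t)|)`.
#'
#' @param src n x 2 matrix of source chromaticities (n >= 10).
#' @param dst n x 2 matrix of destination chromaticities, row-matched to
#'   `src`.
#' @param cfg An [irls_config()].
#' @param method `"l1"` (default, IRLS) or `"ols"` (single unweighted
#'   least-squares solve; used as a comparison baseline).
#' @return A `poly_color_model`.
#' @export
fit_color_model <- function(src, dst, cfg = irls_config(),
                            method = c("l1", "ols")) {
  method <- match.arg(method)
  src <- .as_uv_matrix(src); dst <- .as_uv_matrix(dst)
  if (nrow(src) != nrow(dst)) stop("src and dst must have equal length")
  if (nrow(src) < 10L)
    stop("need at least 10 correspondences to determine 10 coefficients, got ",
         nrow(src))
  stopifnot(inherits(cfg, "irls_config"))
  X <- uv_design(src)
  if (method == "ols") {
    fit <- qr(X)
    if (fit$rank < ncol(X)) stop("design matrix is rank deficient")
    return(poly_color_model(qr.coef(fit, dst[, 1]), qr.coef(fit, dst[, 2])))
  }
  poly_color_model(.irls_lad(X, dst[, 1], cfg),
                   .irls_lad(X, dst[, 2], cfg))
}

#' L1 cost of a model on a correspondence set
#'
#' `sum_i (|du_i| + |dv_i|)` between `apply_color_model(model, src)` and
#' `dst`; the objective the IRLS fit approximately minimizes (summed over
#' both channels).
#'
#' @inheritParams fit_color_model
#' @param model A `poly_color_model`.
#' @return Scalar cost.
#' @export
model_l1_cost <- function(model, src, dst) {
  pred <- apply_color_model(model, src)
  sum(abs(pred - .as_uv_matrix(dst)))
}

#' Serialize / deserialize a polynomial color model as JSON
#'
#' Schema: `{"a_u": [10], "a_v": [10], "basis": "uv-poly3-v1"}` where the
#' basis tag pins the monomial order of [uv_design()].
#'
#' @param model A `poly_color_model`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return `model_to_json`: JSON string (invisibly, if written to a file).
#' @export
model_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "poly_color_model"))
  js <- jsonlite::toJSON(list(a_u = model$a_u, a_v = model$a_v,
                              basis = "uv-poly3-v1"),
                         auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname model_to_json
#' @param json JSON string or path to a JSON file.
#' @return `model_from_json`: a `poly_color_model`.
#' @export
model_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  if (!identical(x$basis, "uv-poly3-v1"))
    stop("unknown basis tag: ", x$basis)
  poly_color_model(x$a_u, x$a_v)
}
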