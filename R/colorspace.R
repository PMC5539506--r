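# sRGB (IEC 61966-2-1, D65) <-> CIE 1976 u'v' chromaticity.
#
# All fitting and matching in this package happens on (u', v') pairs; RGB only
# appears at the image boundary. Colors travel as n x 2 matrices with columns
# u, v ("uv matrices"); RGB as n x 3 matrices of 8-bit values in [0, 255].

# sRGB -> XYZ matrix for the D65 white point (linear-light RGB in [0,1]).
.SRGB2XYZ <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041), nrow = 3, byrow = TRUE)

.XYZ2SRGB <- solve(.SRGB2XYZ)

#' D65 white point chromaticity
#'
#' The (u', v') coordinates of the D65 white point under the standard sRGB
#' primaries; also the value returned for the degenerate pure-black input.
#'
#' @return Numeric vector `c(u, v)`.
#' @export
uv_white_d65 <- function() {
  xyz <- as.vector(.SRGB2XYZ %*% c(1, 1, 1))
  d <- xyz[1] + 15 * xyz[2] + 3 * xyz[3]
  c(u = 4 * xyz[1] / d, v = 9 * xyz[2] / d)
}

.srgb_decode <- function(x) {
  # x in [0,1] gamma-encoded -> linear
  ifelse(x <= 0.04045, x / 12.92, ((x + 0.055) / 1.055)^2.4)
}

.srgb_encode <- function(x) {
  ifelse(x <= 0.0031308, 12.92 * x, 1.055 * x^(1 / 2.4) - 0.055)
}

.as_rgb_matrix <- function(rgb) {
  if (is.null(dim(rgb))) rgb <- matrix(rgb, nrow = 1)
  rgb <- as.matrix(rgb)
  stopifnot(ncol(rgb) == 3)
  if (any(!is.finite(rgb)) || any(rgb < 0) || any(rgb > 255))
    stop("RGB values must be finite and within [0, 255]")
  rgb
}

.as_uv_matrix <- function(uv) {
  if (is.null(dim(uv))) uv <- matrix(uv, nrow = 1)
  uv <- as.matrix(uv)
  stopifnot(ncol(uv) == 2)
  if (any(!is.finite(uv))) stop("u'v' values must be finite")
  uv
}

#' Convert 8-bit sRGB colors to CIE 1976 u'v' chromaticity
#'
#' Decodes the sRGB transfer function, converts linear RGB to XYZ with the
#' standard D65 matrix, and projects to the uniform chromaticity scale:
#' u' = 4X / (X + 15Y + 3Z), v' = 9Y / (X + 15Y + 3Z).
#'
#' Pure black has no chromaticity (zero denominator); it maps to the D65
#' white point with a warning so downstream fits never see non-finite values.
#'
#' @param rgb Numeric vector of length 3 or n x 3 matrix, channels in
#'   \[0, 255\].
#' @return n x 2 matrix with columns `u`, `v`.
#' @export
#' @examples
#' rgb_to_uv(c(255, 255, 255))  # D65 white point
rgb_to_uv <- function(rgb) {
  rgb <- .as_rgb_matrix(rgb)
  lin <- .srgb_decode(rgb / 255)
  linear_rgb_to_uv(lin)
}

#' Convert linear-light RGB (in \[0,1\]) to u'v'
#'
#' @param lin n x 3 matrix of linear RGB values.
#' @return n x 2 matrix with columns `u`, `v`.
#' @export
linear_rgb_to_uv <- function(lin) {
  if (is.null(dim(lin))) lin <- matrix(lin, nrow = 1)
  xyz <- lin %*% t(.SRGB2XYZ)
  d <- xyz[, 1] + 15 * xyz[, 2] + 3 * xyz[, 3]
  bad <- d <= 0
  d[bad] <- 1  # avoid 0/0; rows overwritten below
  out <- cbind(u = 4 * xyz[, 1] / d, v = 9 * xyz[, 2] / d)
  if (any(bad)) {
    warning("pure black input has undefined chromaticity; ",
            "returning D65 white point for ", sum(bad), " color(s)")
    w <- uv_white_d65()
    out[bad, 1] <- w[1]
    out[bad, 2] <- w[2]
  }
  out
}

#' Render u'v' chromaticities as 8-bit sRGB at a fixed luminance
#'
#' Inverts the chromaticity projection at luminance `Y`, converts XYZ to
#' linear sRGB and gamma-encodes. Out-of-gamut channels are clipped to
#' \[0, 255\]; no error is raised (documented clipping policy). Used for
#' rendering synthetic scenes and diagnostic color swatches.
#'
#' @param uv Numeric vector `c(u, v)` or n x 2 matrix.
#' @param luminance_Y Relative luminance in (0, 1\].
#' @return n x 3 integer-valued matrix of 8-bit sRGB channels.
#' @export
uv_to_rgb_display <- function(uv, luminance_Y = 1) {
  stopifnot(is.numeric(luminance_Y), length(luminance_Y) %in% c(1L, nrow(.as_uv_matrix(uv))),
            all(luminance_Y > 0), all(luminance_Y <= 1))
  uv <- .as_uv_matrix(uv)
  u <- uv[, 1]; v <- uv[, 2]
  if (any(v <= 0)) stop("v' must be positive to recover XYZ")
  Y <- rep_len(luminance_Y, nrow(uv))
  X <- 9 * u / (4 * v) * Y
  Z <- (12 - 3 * u - 20 * v) / (4 * v) * Y
  lin <- cbind(X, Y, Z) %*% t(.XYZ2SRGB)
  lin[lin < 0] <- 0
  lin[lin > 1] <- 1
  out <- round(255 * .srgb_encode(lin))
  out[out < 0] <- 0
  out[out > 255] <- 255
  colnames(out) <- c("r", "g", "b")
  out
}

#' Check whether u'v' chromaticities are inside the sRGB gamut at luminance Y
#'
#' @inheritParams uv_to_rgb_display
#' @return Logical vector.
#' @export
uv_in_gamut <- function(uv, luminance_Y = 1) {
  uv <- .as_uv_matrix(uv)
  u <- uv[, 1]; v <- uv[, 2]
  Y <- rep_len(luminance_Y, nrow(uv))
  X <- 9 * u / (4 * v) * Y
  Z <- (12 - 3 * u - 20 * v) / (4 * v) * Y
  lin <- cbind(X, Y, Z) %*% t(.XYZ2SRGB)
  apply(lin >= 0 & lin <= 1, 1, all)
}

#' Average a set of pixel colors into one chromaticity
#'
#' A patch color is the mean of many pixels. Because chromaticity is a ratio
#' of tristimulus values, the mean is taken in linear RGB by default and then
#' converted, rather than averaging u'v' coordinates directly; `space = "uv"`
#' selects the alternative (averaging after conversion), retained because the
#' two differ only at second order for near-uniform patches.
#'
#' @param rgb n x 3 matrix of 8-bit sRGB pixel values.
#' @param space `"linear-rgb"` (default) or `"uv"`.
#' @return Length-2 vector `c(u, v)`.
#' @export
average_patch_color <- function(rgb, space = c("linear-rgb", "uv")) {
  space <- match.arg(space)
  rgb <- .as_rgb_matrix(rgb)
  if (space == "linear-rgb") {
    lin <- .srgb_decode(rgb / 255)
    drop(linear_rgb_to_uv(matrix(colMeans(lin), nrow = 1)))
  } else {
    colMeans(rgb_to_uv(rgb))
  }
}
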