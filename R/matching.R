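# Measurement: adapt a new capture into the calibration frame and estimate
# pH by best L1 match against the high-resolution curves.

#' One measurement capture
#'
#' @param reference 216 x 2 matrix of reference-grid chromaticities (same
#'   ordering convention as [chart_capture()]).
#' @param target 4 x 2 matrix of raw strip-patch chromaticities.
#' @return Object of class `measurement_capture`.
#' @export
measurement_capture <- function(reference, target) {
  reference <- .as_uv_matrix(reference)
  target <- .as_uv_matrix(target)
  if (nrow(reference) != 216L)
    stop("reference grid must have 216 colors, got ", nrow(reference))
  if (nrow(target) != 4L)
    stop("target must have 4 patch colors, got ", nrow(target))
  structure(list(reference = reference, target = target),
            class = "measurement_capture")
}

#' Estimate pH from a measurement capture
#'
#' Fits the adaptation model `F_M` from the capture's reference colors to the
#' stored pivot reference colors, applies it to the four raw patch colors,
#' and scans the calibrated curves: for every grid pH p the cost is
#' `sum_k (|du_k| + |dv_k|)` between the adapted patch colors and the curve
#' colors at p. The estimate is the grid argmin; exact ties break toward the
#' lowest p (deterministic).
#'
#' @param capture A [measurement_capture()].
#' @param calib A `calibration_data` from [calibrate()] or
#'   [read_calibration()].
#' @param irls An [irls_config()].
#' @param refine If `TRUE`, additionally reports `ph_refined`, a parabolic
#'   interpolation of the cost minimum between neighboring grid points.
#'   Off by default: the estimate of record is the 0.1-grid value.
#' @return Object of class `ph_estimate`: `ph`, `match_cost`,
#'   `per_patch_cost` (length 4 at the argmin), `raw_target`,
#'   `calibrated_target` (4 x 2), `cost_profile` (length of the grid),
#'   `grid`, and optionally `ph_refined`.
#' @export
measure <- function(capture, calib, irls = irls_config(), refine = FALSE) {
  stopifnot(inherits(capture, "measurement_capture"),
            inherits(calib, "calibration_data"))
  if (length(calib$grid) == 0L || length(calib$curves) != 4L)
    stop("calibration data has an empty grid or missing curves")
  FM <- fit_color_model(capture$reference, calib$pivot_reference, cfg = irls)
  adapted <- apply_color_model(FM, capture$target)
  per_patch <- vapply(1:4, function(k) {
    d <- abs(sweep(calib$curves[[k]], 2, adapted[k, ]))
    d[, 1] + d[, 2]
  }, numeric(length(calib$grid)))           # grid x 4
  profile <- rowSums(per_patch)
  best <- which.min(profile)                # which.min takes the first == lowest p
  out <- list(ph = calib$grid[best], match_cost = profile[best],
              per_patch_cost = per_patch[best, ],
              raw_target = capture$target, calibrated_target = adapted,
              cost_profile = profile, grid = calib$grid, model = FM)
  if (refine) {
    if (best > 1L && best < length(profile)) {
      y0 <- profile[best - 1]; y1 <- profile[best]; y2 <- profile[best + 1]
      denom <- y0 - 2 * y1 + y2
      shift <- if (denom > 0) 0.5 * (y0 - y2) / denom else 0
      out$ph_refined <- calib$grid[best] +
        shift * (calib$grid[2] - calib$grid[1])
    } else out$ph_refined <- calib$grid[best]
  }
  structure(out, class = "ph_estimate")
}

#' @export
print.ph_estimate <- function(x, ...) {
  cat(sprintf("pH estimate: %.1f (match cost %.4g)\n", x$ph, x$match_cost))
  invisible(x)
}

#' Round half away from zero at a given number of decimals
#'
#' Plain `round()` rounds half to even and is subject to binary
#' representation error; replicate tables are printed with half-up rounding
#' of exact decimal quantities, so the statistics below are computed in
#' integer hundredths and rounded half-up.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Replicate statistics for repeated strip readings
#'
#' Given replicate pH estimates of the same sample and the sample's ideal
#' (reference) pH, returns the mean absolute error and the *population*
#' standard deviation (divisor n) of the estimates, both rounded half-up to
#' two decimals. Estimates and ideal values carry at most two decimals, so
#' the statistics are computed exactly in integer hundredths before
#' rounding.
#'
#' @param estimates Numeric vector of replicate pH estimates (or a list of
#'   `ph_estimate` objects), length >= 1.
#' @param ideal_ph The reference pH of the measured sample.
#' @return Named numeric vector `c(avg_abs_error, std_dev)`.
#' @export
summarize_replicates <- function(estimates, ideal_ph) {
  if (is.list(estimates))
    estimates <- vapply(estimates, function(e) {
      stopifnot(inherits(e, "ph_estimate"))
      e$ph
    }, numeric(1))
  stopifnot(is.numeric(estimates), is.numeric(ideal_ph),
            length(ideal_ph) == 1L)
  if (length(estimates) == 0L) stop("need at least one replicate estimate")
  e100 <- round(estimates * 100)
  i100 <- round(ideal_ph * 100)
  avg <- mean(abs(e100 - i100)) / 100
  sdev <- sqrt(mean((e100 - mean(e100))^2)) / 100
  c(avg_abs_error = round_half_up(avg, 2), std_dev = round_half_up(sdev, 2))
}

#' Bundled four-replicate buffer readings
#'
#' A small validation dataset of pH strip readings: three handsets (A, B, C)
#' each captured strips wetted with standard buffer solutions four times;
#' the table lists the four per-capture estimates, the reference pH of each
#' buffer, and the published summary statistics.
#'
#' @return A data.frame with columns `phone`, `sample`, `ideal_ph`,
#'   `rep1`..`rep4`, `avg_abs_err`, `std_dev`.
#' @export
buffer_replicates <- function() {
  read.csv(system.file("extdata", "buffer_replicates.csv",
                       package = "phstrip", mustWork = TRUE),
           stringsAsFactors = FALSE)
}
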