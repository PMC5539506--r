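# Calibration: from the 15 comparison-chart captures (one per integer pH) to
# the stored calibration product -- the pivot capture's reference colors and
# four high-resolution pH-color curves on a 0.1 pH grid.

#' Spline configuration for the pH-color curves
#'
#' @param lambda_smooth Smoothing weight of the curvature penalty. The
#'   default 3/7 weights data misfit against smoothness roughly 7:3 on
#'   typical indicator curves; `0` interpolates the knots exactly and very
#'   large values tend to a straight line.
#' @param grid_start,grid_stop,grid_step Evaluation grid of the curves in pH
#'   units; defaults 0.0 to 14.0 in steps of 0.1 (141 points).
#' @return Object of class `spline_config`.
#' @export
spline_config <- function(lambda_smooth = 3 / 7, grid_start = 0,
                          grid_stop = 14, grid_step = 0.1) {
  stopifnot(is.numeric(lambda_smooth), length(lambda_smooth) == 1L)
  if (lambda_smooth < 0) stop("lambda_smooth must be >= 0")
  stopifnot(grid_stop > grid_start, grid_step > 0)
  n_step <- (grid_stop - grid_start) / grid_step
  if (abs(n_step - round(n_step)) > 1e-9)
    stop("grid_step must divide the grid range")
  structure(list(lambda_smooth = lambda_smooth, grid_start = grid_start,
                 grid_stop = grid_stop, grid_step = grid_step),
            class = "spline_config")
}

#' @rdname spline_config
#' @param cfg A `spline_config`.
#' @return `spline_grid`: the numeric evaluation grid.
#' @export
spline_grid <- function(cfg) {
  stopifnot(inherits(cfg, "spline_config"))
  n <- round((cfg$grid_stop - cfg$grid_start) / cfg$grid_step)
  cfg$grid_start + cfg$grid_step * 0:n
}

#' One comparison-chart capture
#'
#' @param ph_index Integer pH index of the chart piece, 0..14.
#' @param reference 216 x 2 matrix of reference-grid chromaticities in
#'   row-major grid order (row i = 1..12, column j = 1..18; rows 1-6 are the
#'   upper reference rectangle, 7-12 the lower).
#' @param target 4 x 2 matrix of strip-patch chromaticities (k = 1..4).
#' @return Object of class `chart_capture`.
#' @export
chart_capture <- function(ph_index, reference, target) {
  reference <- .as_uv_matrix(reference)
  target <- .as_uv_matrix(target)
  stopifnot(length(ph_index) == 1L, ph_index == round(ph_index),
            ph_index >= 0, ph_index <= 14)
  if (nrow(reference) != 216L)
    stop("reference grid must have 216 (= 12 x 18) colors, got ",
         nrow(reference))
  if (nrow(target) != 4L)
    stop("target must have 4 patch colors, got ", nrow(target))
  structure(list(ph_index = as.integer(ph_index), reference = reference,
                 target = target),
            class = "chart_capture")
}

#' Interpolate one patch's pH-color curve
#'
#' Fits the vector-valued curve f(P) through the 15 calibrated patch colors
#' minimizing `sum_P ||c_P - f(P)||^2 + lambda * integral ||f''||^2`. The
#' squared norm separates over coordinates, so the minimizer is two
#' independent scalar cubic smoothing splines (natural boundary) over the
#' knots P = 0..14, evaluated on the 0.1 grid.
#'
#' @param points 15 x 2 matrix of calibrated patch chromaticities, row P+1
#'   holding the color at integer pH P.
#' @param spline A [spline_config()].
#' @return m x 2 matrix of curve chromaticities on the grid (141 rows for
#'   the default grid).
#' @export
interpolate_curve <- function(points, spline = spline_config()) {
  points <- .as_uv_matrix(points)
  stopifnot(inherits(spline, "spline_config"))
  if (nrow(points) != 15L)
    stop("expected 15 knot colors (pH 0..14), got ", nrow(points))
  p_knots <- 0:14
  grid <- spline_grid(spline)
  fu <- smoothing_spline_fit(p_knots, points[, 1], spline$lambda_smooth)
  fv <- smoothing_spline_fit(p_knots, points[, 2], spline$lambda_smooth)
  cbind(u = smoothing_spline_eval(fu, grid),
        v = smoothing_spline_eval(fv, grid))
}

#' Build the calibration data from the 15 chart captures
#'
#' For every pH index P the color-converting model `F_P` is fitted from that
#' capture's 216 reference colors to the pivot capture's reference colors and
#' applied to the capture's 4 strip-patch colors, giving the calibrated
#' target colors; the pivot capture runs through its own (near-identity)
#' fitted model so all 15 are processed uniformly. Each patch's 15 calibrated
#' colors are then interpolated to the high-resolution curve.
#'
#' @param captures List of 15 [chart_capture()] objects, one per integer pH
#'   0..14 (any order).
#' @param pivot Pivot pH index whose reference colors define the common
#'   frame; default 7.
#' @param spline A [spline_config()].
#' @param irls An [irls_config()].
#' @return Object of class `calibration_data`: `pivot`, `pivot_reference`
#'   (216 x 2), `calibrated_targets` (15 x 2 per patch, the spline knots),
#'   `curves` (list of 4 matrices, grid length x 2), `grid`, `fit_residuals`
#'   (per-P mean absolute adaptation residual), `energy` (per patch/channel
#'   realized error/smoothness energies).
#' @export
calibrate <- function(captures, pivot = 7L, spline = spline_config(),
                      irls = irls_config()) {
  stopifnot(is.list(captures))
  idx <- vapply(captures, function(cc) {
    stopifnot(inherits(cc, "chart_capture"))
    cc$ph_index
  }, integer(1))
  missing <- setdiff(0:14, idx)
  if (length(missing) > 0)
    stop("missing chart capture(s) for pH index(es): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(idx))
    stop("duplicate chart capture(s) for pH index(es): ",
         paste(unique(idx[duplicated(idx)]), collapse = ", "))
  if (!pivot %in% idx) stop("pivot index ", pivot, " not among captures")
  ord <- order(idx)
  captures <- captures[ord]
  pivot_ref <- captures[[which(sort(idx) == pivot)]]$reference

  calib_t <- matrix(NA_real_, 15, 8)  # per P: 4 patches x (u, v)
  resid <- numeric(15)
  for (P in 0:14) {
    cc <- captures[[P + 1]]
    FP <- fit_color_model(cc$reference, pivot_ref, cfg = irls)
    resid[P + 1] <- model_l1_cost(FP, cc$reference, pivot_ref) / (2 * 216)
    ct <- apply_color_model(FP, cc$target)
    calib_t[P + 1, ] <- as.vector(t(ct))
  }
  knots <- lapply(1:4, function(k)
    cbind(u = calib_t[, 2 * k - 1], v = calib_t[, 2 * k]))
  curves <- lapply(knots, interpolate_curve, spline = spline)
  energy <- lapply(knots, function(pts) {
    fu <- smoothing_spline_fit(0:14, pts[, 1], spline$lambda_smooth)
    fv <- smoothing_spline_fit(0:14, pts[, 2], spline$lambda_smooth)
    eu <- smoothing_spline_energy(fu); ev <- smoothing_spline_energy(fv)
    list(error = eu$error + ev$error, smooth = eu$smooth + ev$smooth)
  })
  structure(list(pivot = as.integer(pivot), pivot_reference = pivot_ref,
                 calibrated_targets = knots, curves = curves,
                 grid = spline_grid(spline), spline = spline,
                 fit_residuals = resid, energy = energy),
            class = "calibration_data")
}

#' @export
print.calibration_data <- function(x, ...) {
  cat("calibration_data: pivot pH", x$pivot, "|",
      nrow(x$pivot_reference), "reference colors |",
      length(x$curves), "patch curves x", length(x$grid), "grid points\n")
  cat("  mean adaptation residual (u'v'):",
      format(mean(x$fit_residuals), digits = 3), "\n")
  invisible(x)
}

#' Write / read calibration data as JSON
#'
#' Schema:
#' `{"pivot": 7, "pivot_reference": [[u,v] x 216 row-major],`
#' `"curves": [[[u,v] x 141] x 4],`
#' `"grid": {"start": 0, "stop": 14, "step": 0.1}}`.
#'
#' @param calib A `calibration_data`.
#' @param path Output / input file path.
#' @return `read_calibration`: a `calibration_data` (without fit
#'   diagnostics, which are not serialized).
#' @export
write_calibration <- function(calib, path) {
  stopifnot(inherits(calib, "calibration_data"))
  obj <- list(
    pivot = calib$pivot,
    pivot_reference = unname(calib$pivot_reference),
    curves = lapply(calib$curves, unname),
    grid = list(start = calib$spline$grid_start,
                stop = calib$spline$grid_stop,
                step = calib$spline$grid_step))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  spl <- spline_config(grid_start = x$grid$start, grid_stop = x$grid$stop,
                       grid_step = x$grid$step)
  pr <- x$pivot_reference
  colnames(pr) <- c("u", "v")
  # jsonlite simplifies the list of equally-shaped curves to a 4 x m x 2
  # array; re-split it into per-patch matrices
  if (is.array(x$curves) && length(dim(x$curves)) == 3L) {
    curves <- lapply(seq_len(dim(x$curves)[1]),
                     function(k) x$curves[k, , ])
  } else {
    curves <- x$curves
  }
  curves <- lapply(curves, function(m) {
    m <- as.matrix(m)
    colnames(m) <- c("u", "v")
    m
  })
  structure(list(pivot = as.integer(x$pivot), pivot_reference = pr,
                 calibrated_targets = NULL, curves = curves,
                 grid = spline_grid(spl), spline = spl,
                 fit_residuals = NULL, energy = NULL),
            class = "calibration_data")
}

#' Export the calibrated curves as CSV
#'
#' Long format with columns `p` (pH), `k` (patch), `u`, `v`; convenient for
#' plotting the pH-color trajectories.
#'
#' @param calib A `calibration_data`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
export_curves_csv <- function(calib, path) {
  stopifnot(inherits(calib, "calibration_data"))
  rows <- do.call(rbind, lapply(seq_along(calib$curves), function(k)
    data.frame(p = calib$grid, k = k,
               u = calib$curves[[k]][, 1], v = calib$curves[[k]][, 2])))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
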