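# Synthetic light-box scenes with known ground truth. The renderer draws
# the canonical scene -- two 6 x 18 reference grids above and below a
# four-patch indicator strip, every cell outlined in black -- applies a
# camera model (geometric pose jitter, chromaticity distortion, brightness
# gain, sensor noise) and reports ground-truth positions and colors so every
# stage of the pipeline can be tested without hardware.

# canonical scene geometry, in scene pixels (image 960 x 720)
.SCENE <- list(
  width = 960L, height = 720L,
  ref_cell_w = 30, ref_cell_h = 24,           # 18 x 6 cells, aspect 3.75
  upper_origin = c(210, 72),                  # (x, y) of upper rectangle
  lower_origin = c(210, 504),
  target_side = 70,
  target_centers_x = c(345, 435, 525, 615),   # strip along y = 360
  target_center_y = 360,
  border_half = 2,                            # black stroke half-width
  background = c(205, 205, 205),
  stroke = c(30, 30, 30),
  luminance = 0.22)                           # render luminance Y

#' Canonical synthetic scene geometry
#'
#' Ground-truth layout constants of the rendered scene (cell sizes, region
#' origins, stroke width, render luminance). Exposed for tests.
#'
#' @return Named list of geometry constants.
#' @export
scene_geometry <- function() .SCENE

.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Deterministic master palette and strip color model
#'
#' The 216 reference colors are a regular 12 x 18 lattice in u'v' (with a
#' small seeded jitter), spaced > 0.01 apart so the polynomial fits are
#' well conditioned, all inside the sRGB gamut at the render luminance.
#' The strip model gives each of the four patches a smooth non-linear
#' pH-color trajectory: anchors at integer pH from low-frequency sinusoids
#' in u'v', joined by natural cubic spline interpolation (so the model is
#' continuous in pH and piecewise-cubic through its anchors).
#'
#' @param seed Integer seed controlling the palette jitter.
#' @return Object of class `strip_palette` with `reference_uv` (216 x 2,
#'   row-major grid order), `reference_rgb` (216 x 3 as drawn), `anchors`
#'   (list of 4 15 x 2 matrices), and `luminance`.
#' @export
default_palette <- function(seed = 1L) {
  jit <- .with_seed(seed, matrix(runif(216 * 2, -4e-4, 4e-4), 216, 2))
  u0 <- 0.155; v0 <- 0.398; step <- 0.011
  grid <- expand.grid(j = 1:18, i = 1:12)  # j fastest: row-major i-then-j
  uv <- cbind(u = u0 + step * (grid$j - 1), v = v0 + step * (grid$i - 1)) +
    jit
  if (!all(uv_in_gamut(uv, .SCENE$luminance)))
    stop("internal error: palette leaves the sRGB gamut")
  omega <- c(0.35, 0.42, 0.48, 0.55)
  phi <- c(0.3, 1.7, 3.1, 4.6)
  nu <- c(0.50, 0.40, 0.55, 0.45)
  psi <- c(1.2, 4.2, 2.4, 5.6)
  anchors <- lapply(1:4, function(k) {
    P <- 0:14
    cbind(u = 0.23 + 0.06 * sin(phi[k] + omega[k] * P),
          v = 0.44 + 0.04 * cos(psi[k] + nu[k] * P))
  })
  structure(list(reference_uv = uv,
                 reference_rgb = uv_to_rgb_display(uv, .SCENE$luminance),
                 anchors = anchors, luminance = .SCENE$luminance,
                 seed = as.integer(seed)),
            class = "strip_palette")
}

#' Strip patch colors at a given pH
#'
#' Evaluates the palette's four patch trajectories at a (possibly
#' fractional) pH by natural cubic spline interpolation of the integer-pH
#' anchors.
#'
#' @param palette A [default_palette()].
#' @param ph pH value in \[0, 14\].
#' @return 4 x 2 matrix of u'v' patch colors.
#' @export
strip_colors <- function(palette, ph) {
  stopifnot(inherits(palette, "strip_palette"),
            is.numeric(ph), length(ph) == 1L, ph >= 0, ph <= 14)
  t(vapply(palette$anchors, function(a) {
    fu <- smoothing_spline_fit(0:14, a[, 1], 0)
    fv <- smoothing_spline_fit(0:14, a[, 2], 0)
    c(smoothing_spline_eval(fu, ph), smoothing_spline_eval(fv, ph))
  }, numeric(2)))
}

#' Camera model for synthetic captures
#'
#' Emulates the uncontrolled parts of a smartphone capture: pose jitter
#' (translation, rotation, scale about the image center), a chromaticity
#' distortion standing in for the built-in automatic color processing,
#' a brightness gain, and additive Gaussian sensor noise. The distortion is
#' either a polynomial map in u'v' (`mode = "uv-poly"`, the family the
#' adaptation step can represent exactly) or an out-of-family channel-wise
#' gamma plus 3 x 3 matrix in linear RGB (`mode = "rgb"`).
#'
#' @param distortion A `poly_color_model` (ignored when `mode = "rgb"`);
#'   default identity.
#' @param brightness_gain Scalar gain > 0 on linear luminance.
#' @param noise_sigma Additive Gaussian noise s.d. in 8-bit units.
#' @param translation Length-2 pixel shift `c(dx, dy)`.
#' @param rotation_deg Rotation in degrees about the image center.
#' @param scale Scale factor about the image center.
#' @param mode `"uv-poly"` or `"rgb"`.
#' @param rgb_matrix,rgb_gamma Out-of-family distortion parameters
#'   (`mode = "rgb"`): 3 x 3 mixing matrix applied in linear RGB, then
#'   per-channel exponent.
#' @return Object of class `camera_model`.
#' @export
camera_model <- function(distortion = identity_color_model(),
                         brightness_gain = 1, noise_sigma = 0,
                         translation = c(0, 0), rotation_deg = 0, scale = 1,
                         mode = c("uv-poly", "rgb"),
                         rgb_matrix = diag(3), rgb_gamma = c(1, 1, 1)) {
  mode <- match.arg(mode)
  stopifnot(inherits(distortion, "poly_color_model"),
            brightness_gain > 0, noise_sigma >= 0,
            length(translation) == 2L, length(rotation_deg) == 1L,
            scale > 0, all(dim(rgb_matrix) == c(3, 3)),
            length(rgb_gamma) == 3L, all(rgb_gamma > 0))
  structure(list(distortion = distortion, brightness_gain = brightness_gain,
                 noise_sigma = noise_sigma, translation = translation,
                 rotation_deg = rotation_deg, scale = scale, mode = mode,
                 rgb_matrix = rgb_matrix, rgb_gamma = rgb_gamma),
            class = "camera_model")
}

#' Random mild camera model
#'
#' Draws (from the current RNG) a per-capture camera: polynomial u'v'
#' distortion with every one of the 20 coefficients perturbed uniformly
#' within `distortion_scale` of the identity model, small pose jitter, and
#' sensor noise.
#'
#' @param distortion_scale Half-width of the uniform coefficient
#'   perturbation (default 0.05, i.e. within 5% of the identity).
#' @param noise_sigma Sensor noise s.d. in 8-bit units.
#' @param max_shift,max_rot Pose jitter bounds (pixels, degrees).
#' @param scale_range Range of the scale factor.
#' @return A `camera_model`.
#' @export
random_camera <- function(distortion_scale = 0.05, noise_sigma = 2,
                          max_shift = 12, max_rot = 4,
                          scale_range = c(0.94, 1.05)) {
  idm <- identity_color_model()
  dist <- poly_color_model(
    idm$a_u + runif(10, -distortion_scale, distortion_scale),
    idm$a_v + runif(10, -distortion_scale, distortion_scale))
  camera_model(distortion = dist, noise_sigma = noise_sigma,
               translation = runif(2, -max_shift, max_shift),
               rotation_deg = runif(1, -max_rot, max_rot),
               scale = runif(1, scale_range[1], scale_range[2]))
}

# forward pose transform: scene coords -> image coords
.pose_forward <- function(xy, camera, sc = .SCENE) {
  th <- camera$rotation_deg * pi / 180
  ctr <- c((sc$width - 1) / 2, (sc$height - 1) / 2)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sweep(sweep(xy, 2, ctr) %*% t(R) * camera$scale, 2,
        ctr + camera$translation, `+`)
}

# distort patch colors and realize them as drawn 8-bit RGB
.drawn_rgb <- function(uv, camera, luminance) {
  Y <- min(1, luminance * camera$brightness_gain)
  if (camera$mode == "uv-poly") {
    duv <- apply_color_model(camera$distortion, uv)
    uv_to_rgb_display(duv, Y)
  } else {
    lin <- .srgb_decode(uv_to_rgb_display(uv, Y) / 255)
    lin <- lin %*% t(camera$rgb_matrix)
    lin[lin < 0] <- 0; lin[lin > 1] <- 1
    lin <- sweep(lin, 2, camera$rgb_gamma, `^`)
    out <- round(255 * .srgb_encode(lin))
    out[out < 0] <- 0; out[out > 255] <- 255
    out
  }
}

# ground-truth cell centers in scene coords, row-major grid order
.scene_positions <- function(sc = .SCENE) {
  cell <- function(origin) {
    g <- expand.grid(j = 1:18, i = 1:6)
    cbind(origin[1] + sc$ref_cell_w * (g$j - 0.5),
          origin[2] + sc$ref_cell_h * (g$i - 0.5))
  }
  list(upper = cell(sc$upper_origin), lower = cell(sc$lower_origin),
       target = cbind(sc$target_centers_x, sc$target_center_y))
}

#' Render a synthetic light-box scene
#'
#' Draws the canonical scene with the given strip patch colors, applies the
#' camera pose, chromaticity distortion, gain and noise, and returns the
#' image with a full ground-truth record. Uses the current RNG for noise;
#' seed the session for reproducible renders.
#'
#' @param palette A [default_palette()].
#' @param camera A [camera_model()].
#' @param strip_uv 4 x 2 matrix of ideal (pre-distortion) patch colors.
#' @return List with `image` (`[720, 960, 3]`) and `truth` (positions of
#'   all 216 + 4 sampling sites in image coordinates, ideal and
#'   post-distortion colors, pose).
#' @export
render_scene <- function(palette, camera = camera_model(), strip_uv) {
  stopifnot(inherits(palette, "strip_palette"),
            inherits(camera, "camera_model"))
  strip_uv <- .as_uv_matrix(strip_uv)
  stopifnot(nrow(strip_uv) == 4L)
  sc <- .SCENE
  w <- sc$width; h <- sc$height
  pos <- .scene_positions(sc)

  # geometry sanity: every region corner must land inside the image
  corners <- rbind(
    cbind(sc$upper_origin[1] + c(0, 540, 540, 0),
          sc$upper_origin[2] + c(0, 0, 144, 144)),
    cbind(sc$lower_origin[1] + c(0, 540, 540, 0),
          sc$lower_origin[2] + c(0, 0, 144, 144)),
    cbind(rep(sc$target_centers_x, each = 4) +
            c(-1, 1, 1, -1) * sc$target_side / 2,
          sc$target_center_y + c(-1, -1, 1, 1) * sc$target_side / 2))
  tc <- .pose_forward(corners, camera)
  if (any(tc[, 1] < 2) || any(tc[, 1] > w - 3) ||
      any(tc[, 2] < 2) || any(tc[, 2] > h - 3))
    stop("camera geometry pushes scene regions off the image")

  # inverse pose: image pixel centers -> scene coordinates
  th <- camera$rotation_deg * pi / 180
  ctr_x <- (w - 1) / 2; ctr_y <- (h - 1) / 2
  px <- rep(0:(w - 1), each = h)   # column-major over [h, w]
  py <- rep(0:(h - 1), times = w)
  dx <- (px - ctr_x - camera$translation[1]) / camera$scale
  dy <- (py - ctr_y - camera$translation[2]) / camera$scale
  sx <- cos(th) * dx + sin(th) * dy + ctr_x
  sy <- -sin(th) * dx + cos(th) * dy + ctr_y

  # color table: 216 reference cells, 4 patches, stroke, background
  drawn_ref <- .drawn_rgb(palette$reference_uv, camera, palette$luminance)
  drawn_tgt <- .drawn_rgb(strip_uv, camera, palette$luminance)
  lut <- rbind(drawn_ref, drawn_tgt, sc$stroke, sc$background)
  i_stroke <- 221L; i_bg <- 222L

  idx <- rep.int(i_bg, w * h)
  bh <- sc$border_half
  for (half in 1:2) {
    org <- if (half == 1) sc$upper_origin else sc$lower_origin
    lx <- sx - org[1]; ly <- sy - org[2]
    inside <- lx >= 0 & lx < 540 & ly >= 0 & ly < 144
    mx <- lx %% sc$ref_cell_w; my <- ly %% sc$ref_cell_h
    border <- inside & (pmin(mx, sc$ref_cell_w - mx) < bh |
                          pmin(my, sc$ref_cell_h - my) < bh)
    cell <- inside & !border
    col <- pmin(pmax(ceiling(lx / sc$ref_cell_w), 1), 18)
    row <- pmin(pmax(ceiling(ly / sc$ref_cell_h), 1), 6)
    offs <- if (half == 1) 0L else 108L
    idx[cell] <- offs + (row[cell] - 1L) * 18L + col[cell]
    idx[border] <- i_stroke
  }
  half_side <- sc$target_side / 2
  for (k in 1:4) {
    lx <- sx - sc$target_centers_x[k]; ly <- sy - sc$target_center_y
    inside <- abs(lx) < half_side & abs(ly) < half_side
    border <- inside & (abs(lx) > half_side - 2 * bh |
                          abs(ly) > half_side - 2 * bh)
    idx[inside & !border] <- 216L + k
    idx[inside & border] <- i_stroke
  }

  img <- array(0, c(h, w, 3))
  for (ch in 1:3) {
    plane <- lut[idx, ch]
    if (camera$noise_sigma > 0)
      plane <- plane + rnorm(w * h, 0, camera$noise_sigma)
    img[, , ch] <- matrix(pmin(pmax(round(plane), 0), 255), h, w)
  }

  truth <- list(
    upper_positions = .pose_forward(pos$upper, camera),
    lower_positions = .pose_forward(pos$lower, camera),
    target_positions = .pose_forward(pos$target, camera),
    reference_uv = palette$reference_uv,
    reference_uv_post = rgb_to_uv(drawn_ref),
    strip_uv = strip_uv,
    strip_uv_post = rgb_to_uv(drawn_tgt),
    camera = camera)
  list(image = img, truth = truth)
}

#' Render a comparison-chart capture (calibration scene)
#'
#' The strip region shows the printed chart piece for one integer pH.
#'
#' @param palette A [default_palette()].
#' @param camera A [camera_model()].
#' @param ph_index Integer pH 0..14.
#' @return List with `image` and `truth` (including `ph`).
#' @export
render_chart_capture <- function(palette, camera = camera_model(),
                                 ph_index) {
  stopifnot(ph_index == round(ph_index), ph_index >= 0, ph_index <= 14)
  out <- render_scene(palette, camera, strip_colors(palette, ph_index))
  out$truth$ph <- as.numeric(ph_index)
  out
}

#' Render a measurement capture (wetted strip scene)
#'
#' @param palette A [default_palette()].
#' @param camera A [camera_model()].
#' @param true_ph pH in \[0, 14\], fractional values allowed.
#' @return List with `image` and `truth` (including `ph`).
#' @export
render_measurement_capture <- function(palette, camera = camera_model(),
                                       true_ph) {
  stopifnot(true_ph >= 0, true_ph <= 14)
  out <- render_scene(palette, camera, strip_colors(palette, true_ph))
  out$truth$ph <- true_ph
  out
}
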