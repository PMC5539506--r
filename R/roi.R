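# Automatic color retrieving: locate the two reference rectangles and the
# four strip patches in a light-box capture and sample their colors.
#
# Six steps: (1) median-filter simplification, (2) Canny edges +
# morphological closing, (3) initial contour extraction (rectangular, convex,
# not small), (4) contour labeling (reference vs target, by aspect ratio and
# distance from the strip's center line), (5) sampling-grid placement from
# the principal axes of each reference contour, (6) color retrieval by
# windowed averaging.
#
# Scene convention (mirrors the physical layout): the strip lies along the
# image's horizontal midline with the two 6 x 18 reference rectangles above
# and below it. The "center line" separating target from reference contours
# is therefore the horizontal midline. Reference grid ordering: rows 1-6 =
# upper rectangle, 7-12 = lower; within a rectangle rows run along the minor
# axis (top to bottom) and columns 1-18 along the major axis, anchored at
# the end nearer the image's left edge. Patches k = 1..4 run along the strip
# axis, same anchoring. Pixel coordinates are 0-based (x right, y down) with
# pixel centers at integer positions.

#' Detection configuration
#'
#' All values the printed chart does not determine (kernel sizes, Canny
#' thresholds, band widths) are empirical; defaults were fixed on the
#' synthetic fixture suite.
#'
#' @param median_kernel Odd median-filter size in pixels (default 5).
#' @param canny_low,canny_high Hysteresis thresholds on the Sobel gradient
#'   magnitude (8-bit scale; defaults 40 / 120).
#' @param morph_kernel Side of the square closing element (odd; default 5:
#'   the closing must bridge the gaps non-maximum suppression leaves at
#'   corners and along staircased diagonal edges, which exceed one pixel).
#' @param min_contour_area Minimum contour area as a fraction of image area
#'   (default 5e-4).
#' @param aspect_ratio_min Minimum side-length aspect ratio of a reference
#'   rectangle (default 3.5; the printed reference paper is 30 x 8 mm,
#'   aspect 3.75).
#' @param target_aspect_max Maximum aspect ratio of a square-like target
#'   patch (default 1.3).
#' @param center_band Fraction of the image height treated as "near the
#'   center line" (default 0.15).
#' @param polygon_epsilon Douglas-Peucker tolerance as a fraction of the
#'   contour perimeter (default 0.02).
#' @param sample_window Half-width in pixels of the color-averaging window;
#'   window side is `2 * sample_window + 1` (default 3).
#' @param frame_inset Signed corrections, in pixels, applied inward to the
#'   reference-frame half extents along the major and minor axes (length 2;
#'   default `c(0, 0)`). Exposed so a systematic localization bias of the
#'   edge tracer relative to the printed boundary can be compensated; the
#'   default side-line corner construction is unbiased to within a pixel on
#'   the synthetic fixture suite.
#' @return Object of class `detection_config`.
#' @export
detection_config <- function(median_kernel = 5L, canny_low = 40,
                             canny_high = 120, morph_kernel = 5L,
                             min_contour_area = 5e-4,
                             aspect_ratio_min = 3.5, target_aspect_max = 1.3,
                             center_band = 0.15, polygon_epsilon = 0.02,
                             sample_window = 3L, frame_inset = c(0, 0)) {
  stopifnot(median_kernel >= 1, median_kernel %% 2 == 1,
            canny_low > 0, canny_high > canny_low,
            morph_kernel >= 1, morph_kernel %% 2 == 1,
            min_contour_area > 0, aspect_ratio_min > 1,
            target_aspect_max >= 1, center_band > 0, center_band < 1,
            polygon_epsilon > 0, sample_window >= 0,
            length(frame_inset) == 2L, all(is.finite(frame_inset)))
  structure(list(median_kernel = as.integer(median_kernel),
                 canny_low = canny_low, canny_high = canny_high,
                 morph_kernel = as.integer(morph_kernel),
                 min_contour_area = min_contour_area,
                 aspect_ratio_min = aspect_ratio_min,
                 target_aspect_max = target_aspect_max,
                 center_band = center_band,
                 polygon_epsilon = polygon_epsilon,
                 sample_window = as.integer(sample_window),
                 frame_inset = frame_inset),
            class = "detection_config")
}

.detection_error <- function(msg, constraint) {
  stop(errorCondition(paste0(msg, " [constraint: ", constraint,
                             "] - re-capture the scene"),
                      constraint = constraint,
                      class = c("phstrip_detection_error", "error")))
}

#' Step 1: noise reduction and image simplification
#'
#' Channel-wise median filter with replicated borders.
#'
#' @param img `[h, w, 3]` image array.
#' @param cfg A [detection_config()].
#' @return Filtered image of the same dimensions.
#' @export
simplify_image <- function(img, cfg = detection_config()) {
  .check_image(img)
  k <- cfg$median_kernel
  out <- img
  for (ch in 1:3) out[, , ch] <- cpp_median_filter(img[, , ch], k)
  out
}

#' Step 2: edge detection
#'
#' Canny edge detection on the luma channel followed by morphological
#' closing to bridge small gaps; the closing merges the twin edge chains of
#' thin printed border strokes into one component.
#'
#' @inheritParams simplify_image
#' @return Binary `[h, w]` matrix (0/1).
#' @export
detect_edges <- function(img, cfg = detection_config()) {
  .check_image(img)
  e <- cpp_canny(image_gray(img), cfg$canny_low, cfg$canny_high)
  cpp_binary_close(e, (cfg$morph_kernel - 1L) %/% 2L)
}

.polygon_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  n <- nrow(v)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

.polygon_centroid <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  n <- nrow(v)
  j <- c(2:n, 1)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-9) return(colMeans(v))
  c(sum((x + x[j]) * cr), sum((y + y[j]) * cr)) / (6 * a)
}

.point_in_polygon <- function(pt, v) {
  # ray casting
  n <- nrow(v)
  j <- c(n, seq_len(n - 1))
  xi <- v[, 1]; yi <- v[, 2]; xj <- v[j, 1]; yj <- v[j, 2]
  cross <- ((yi > pt[2]) != (yj > pt[2])) &
    (pt[1] < (xj - xi) * (pt[2] - yi) / (yj - yi) + xi)
  sum(cross, na.rm = TRUE) %% 2 == 1
}

# Ramer-Douglas-Peucker on an open chain of points
.rdp <- function(pts, eps) {
  n <- nrow(pts)
  if (n <= 2) return(pts)
  a <- pts[1, ]; b <- pts[n, ]
  ab <- b - a
  len <- sqrt(sum(ab^2))
  d <- if (len < 1e-12) {
    sqrt(rowSums(sweep(pts, 2, a)^2))
  } else {
    abs((pts[, 1] - a[1]) * ab[2] - (pts[, 2] - a[2]) * ab[1]) / len
  }
  i <- which.max(d)
  if (d[i] <= eps) return(pts[c(1, n), , drop = FALSE])
  left <- .rdp(pts[1:i, , drop = FALSE], eps)
  right <- .rdp(pts[i:n, , drop = FALSE], eps)
  rbind(left, right[-1, , drop = FALSE])
}

# closed-curve polygon approximation: split at the two mutually farthest
# points (approximated via the farthest point from vertex 1), simplify each
# half
.approx_polygon <- function(boundary, eps) {
  n <- nrow(boundary)
  if (n <= 4) return(boundary)
  d1 <- rowSums(sweep(boundary, 2, boundary[1, ])^2)
  i <- which.max(d1)
  h1 <- .rdp(boundary[1:i, , drop = FALSE], eps)
  h2 <- .rdp(boundary[c(i:n, 1), , drop = FALSE], eps)
  v <- rbind(h1[-nrow(h1), , drop = FALSE], h2[-nrow(h2), , drop = FALSE])
  v
}

# recover the quadrilateral underlying a convex hull: take the four longest
# hull edges (in cyclic order) as the side lines and intersect consecutive
# lines to get the corners. Rasterization chamfers corners and noise adds
# whiskers, so true corners often lie slightly outside the hull; side-line
# intersection restores them, unlike vertex decimation. Returns NULL (with
# the perimeter coverage of the chosen sides attached as an attribute) when
# the construction degenerates.
# drop hull vertices where the boundary turns by less than `ang` degrees:
# rasterized straight sides stair-step into many short near-collinear hull
# edges, which must be merged before the four side lines can be identified
.merge_collinear <- function(v, ang = 5) {
  repeat {
    n <- nrow(v)
    if (n <= 4L) break
    jp <- c(n, seq_len(n - 1)); jn <- c(2:n, 1)
    e1 <- v - v[jp, , drop = FALSE]
    e2 <- v[jn, , drop = FALSE] - v
    s <- (e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]) /
      (sqrt(rowSums(e1^2)) * sqrt(rowSums(e2^2)) + 1e-12)
    turn <- abs(asin(pmin(1, pmax(-1, s)))) * 180 / pi
    flat <- which(turn < ang)
    if (length(flat) == 0L) break
    v <- v[-flat[which.min(turn[flat])], , drop = FALSE]
  }
  v
}

# fraction of traced boundary points lying within `tol` pixels of the
# quadrilateral's perimeter. Convex rectangular outlines adhere almost
# everywhere (small excursions through edge-chain gaps are tolerated);
# genuinely concave shapes such as stars spend much of their boundary deep
# inside their hull and score low.
.boundary_adherence <- function(b, quad, tol = 8) {
  n <- nrow(quad)
  dmin <- rep(Inf, nrow(b))
  for (i in seq_len(n)) {
    a <- quad[i, ]; e <- quad[i %% n + 1, ] - a
    len2 <- sum(e^2)
    t <- ((b[, 1] - a[1]) * e[1] + (b[, 2] - a[2]) * e[2]) / max(len2, 1e-12)
    t <- pmin(pmax(t, 0), 1)
    d <- sqrt((b[, 1] - a[1] - t * e[1])^2 + (b[, 2] - a[2] - t * e[2])^2)
    dmin <- pmin(dmin, d)
  }
  mean(dmin <= tol)
}

.quad_from_hull <- function(hull) {
  hull <- .merge_collinear(hull)
  n <- nrow(hull)
  if (n < 4L) return(NULL)
  jn <- c(2:n, 1)
  len <- sqrt(rowSums((hull[jn, , drop = FALSE] - hull)^2))
  idx <- sort(order(-len)[1:4])  # cyclic order preserved
  coverage <- sum(len[idx]) / sum(len)
  corners <- matrix(0, 4, 2)
  for (t in 1:4) {
    i1 <- idx[t]; i2 <- idx[t %% 4 + 1]
    p1 <- hull[i1, ]; d1 <- hull[jn[i1], ] - p1
    p2 <- hull[i2, ]; d2 <- hull[jn[i2], ] - p2
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-9) return(NULL)
    tt <- ((p2[1] - p1[1]) * d2[2] - (p2[2] - p1[2]) * d2[1]) / den
    corners[t, ] <- p1 + tt * d1
  }
  attr(corners, "coverage") <- coverage
  corners
}

.is_convex <- function(v, tol_frac = 0.05) {
  n <- nrow(v)
  if (n < 3) return(FALSE)
  j <- c(2:n, 1); k <- c(3:n, 1, 2)
  cr <- (v[j, 1] - v[, 1]) * (v[k, 2] - v[j, 2]) -
    (v[j, 2] - v[, 2]) * (v[k, 1] - v[j, 1])
  tol <- tol_frac * max(abs(cr))
  all(cr >= -tol) || all(cr <= tol)
}

.side_lengths <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1)
  sqrt((v[j, 1] - v[, 1])^2 + (v[j, 2] - v[, 2])^2)
}

# aspect ratio of a quadrilateral from opposite side-length means (rotation
# invariant, unlike the bounding box)
.quad_aspect <- function(v) {
  L <- .side_lengths(v)
  s1 <- (L[1] + L[3]) / 2
  s2 <- (L[2] + L[4]) / 2
  max(s1, s2) / min(s1, s2)
}

#' Step 3: initial contour extraction
#'
#' Traces the outer boundary of every connected edge component, simplifies
#' it to a polygon, and keeps quadrilateral, convex contours of sufficient
#' area.
#'
#' @param edges Binary edge map from [detect_edges()].
#' @param cfg A [detection_config()].
#' @return List of contours; each has `vertices` (4 x 2), `boundary`
#'   (dense n x 2), `area`, `centroid`, `aspect`.
#' @export
extract_initial_contours <- function(edges, cfg = detection_config()) {
  min_area <- cfg$min_contour_area * nrow(edges) * ncol(edges)
  comps <- cpp_component_boundaries(edges, min_pixels = 12L)
  out <- list()
  for (cp in comps) {
    b <- cp$xy
    if (nrow(b) < 8) next
    # The traced boundary can spike inward where the edge chain has gaps;
    # the convex hull removes such excursions without moving true corners.
    # Convexity is then judged by solidity (trace area / hull area), which
    # rejects genuinely concave shapes but tolerates thin spikes, and the
    # polygon is simplified from the hull with a tolerance ladder (finest
    # first) until it is a quadrilateral -- rasterized corners of rotated
    # rectangles are chamfered and may need a coarser pass.
    hull <- b[chull(b), , drop = FALSE]
    hull_area <- .polygon_area(hull)
    if (hull_area < min_area) next
    # a rectangle's four sides make up most of the hull perimeter even
    # when rasterized corners are chamfered (coverage ~0.8-1.0), while the
    # four longest edges of a round blob cover only ~4/n of it
    v <- .quad_from_hull(hull)
    if (is.null(v) || attr(v, "coverage") < 0.7) next
    if (!.is_convex(v)) next
    # convexity of the underlying region: the trace must follow the quad
    if (.boundary_adherence(b, v) < 0.6) next
    area <- .polygon_area(v)
    if (area < min_area || area > 1.25 * hull_area) next
    out[[length(out) + 1L]] <- list(vertices = v, boundary = b, area = area,
                                    centroid = .polygon_centroid(v),
                                    aspect = .quad_aspect(v))
  }
  out
}

#' Step 4: contour labeling
#'
#' Separates reference and target contours. After containment
#' de-duplication (the inner edge of a printed border duplicates the outer;
#' the outer is kept), reference candidates are elongated rectangles
#' (aspect > `aspect_ratio_min`) away from the strip's center line; the
#' topmost becomes the upper reference, the bottommost the lower. Target
#' candidates are square-like contours near the center line; a
#' size-consistency filter keeps the largest cluster of areas within 30% of
#' the cluster median, which must contain exactly 4 patches.
#'
#' @param contours List from [extract_initial_contours()].
#' @param cfg A [detection_config()].
#' @param image_dim `c(height, width)` of the source image.
#' @return Object of class `scene_layout` (contours only; see
#'   [place_sampling_grid()]).
#' @export
label_contours <- function(contours, cfg = detection_config(), image_dim) {
  if (length(contours) == 0L)
    .detection_error("no rectangular contours found", "initial-contours")
  h <- image_dim[1]
  # containment de-duplication, outer (larger) kept
  ord <- order(-vapply(contours, `[[`, numeric(1), "area"))
  contours <- contours[ord]
  keep <- rep(TRUE, length(contours))
  for (i in seq_along(contours)) {
    if (!keep[i]) next
    for (j in seq_along(contours)) {
      if (i == j || !keep[j]) next
      if (contours[[j]]$area <= contours[[i]]$area &&
          all(apply(contours[[j]]$vertices, 1, .point_in_polygon,
                    v = contours[[i]]$vertices)))
        keep[j] <- FALSE
    }
  }
  contours <- contours[keep]

  cy <- vapply(contours, function(ct) ct$centroid[2], numeric(1))
  aspect <- vapply(contours, `[[`, numeric(1), "aspect")
  near_center <- abs(cy - h / 2) < 0.5 * cfg$center_band * h

  ref_idx <- which(aspect > cfg$aspect_ratio_min & !near_center)
  if (length(ref_idx) < 2L)
    .detection_error(paste0("found ", length(ref_idx),
                            " reference rectangle(s), need 2"),
                     "reference-count")
  upper <- ref_idx[which.min(cy[ref_idx])]
  lower <- ref_idx[which.max(cy[ref_idx])]
  if (upper == lower)
    .detection_error("reference rectangles are not vertically separated",
                     "reference-separation")

  tgt_idx <- which(aspect <= cfg$target_aspect_max & near_center)
  if (length(tgt_idx) >= 1L) {
    areas <- vapply(contours[tgt_idx], `[[`, numeric(1), "area")
    # largest cluster of mutually similar areas, then +/-30% of its median
    cluster_of <- lapply(areas, function(a)
      which(abs(areas - a) <= 0.3 * a))
    best <- cluster_of[[which.max(lengths(cluster_of))]]
    med <- median(areas[best])
    tgt_idx <- tgt_idx[abs(areas - med) <= 0.3 * med]
  }
  if (length(tgt_idx) != 4L)
    .detection_error(paste0("found ", length(tgt_idx),
                            " target patch contour(s), need 4"),
                     "target-count")

  # order patches along the strip axis, anchored near the image's left edge
  tgt_cx <- vapply(contours[tgt_idx], function(ct) ct$centroid[1], numeric(1))
  tgt_idx <- tgt_idx[order(tgt_cx)]

  structure(list(upper_reference = contours[[upper]],
                 lower_reference = contours[[lower]],
                 targets = contours[tgt_idx],
                 image_dim = image_dim),
            class = "scene_layout")
}

# principal axes of a contour from its polygon vertices; returns unit
# major/minor axes with a deterministic orientation (major points toward
# +x, or +y when near-vertical; minor is major rotated +90 deg). The
# simplified vertices are used rather than the dense traced boundary: the
# trace can detour into the interior through small edge gaps, which biases
# the centroid and tilts the axes, while the corner vertices are exact.
.contour_axes <- function(boundary) {
  ctr <- colMeans(boundary)
  cc <- sweep(boundary, 2, ctr)
  cv <- crossprod(cc) / nrow(cc)
  if (min(diag(cv)) < 1e-12 && abs(cv[1, 2]) < 1e-12)
    stop("degenerate contour: zero variance along a principal axis")
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[2] < 1e-9)
    stop("degenerate contour: zero variance along a principal axis")
  major <- eg$vectors[, 1]
  if (abs(major[1]) >= abs(major[2])) {
    if (major[1] < 0) major <- -major
  } else if (major[2] < 0) major <- -major
  minor <- c(-major[2], major[1])
  if ((abs(minor[1]) >= abs(minor[2]) && minor[1] < 0) ||
      (abs(minor[1]) < abs(minor[2]) && minor[2] < 0))
    minor <- -minor
  list(center = ctr, major = major, minor = minor)
}

# first intersection of the ray ctr + t*dir (t > 0) with a polygon
.ray_polygon_hit <- function(ctr, dir, v) {
  n <- nrow(v)
  j <- c(2:n, 1)
  tbest <- Inf
  for (i in seq_len(n)) {
    a <- v[i, ]; e <- v[j[i], ] - a
    den <- dir[1] * (-e[2]) - dir[2] * (-e[1])
    if (abs(den) < 1e-12) next
    rhs <- a - ctr
    t <- (rhs[1] * (-e[2]) - rhs[2] * (-e[1])) / den
    s <- (dir[1] * rhs[2] - dir[2] * rhs[1]) / den
    if (t > 0 && s >= -1e-9 && s <= 1 + 1e-9) tbest <- min(tbest, t)
  }
  if (!is.finite(tbest)) stop("principal axis does not cross the contour")
  ctr + tbest * dir
}

# 6 x 18 cell-center grid inside one reference rectangle, row-major
# (18 consecutive columns per row)
.reference_grid_positions <- function(contour, nrow_cells = 6L,
                                      ncol_cells = 18L, inset = c(0, 0)) {
  ax <- .contour_axes(contour$vertices)
  v <- contour$vertices
  p_maj <- rbind(.ray_polygon_hit(ax$center, -ax$major, v),
                 .ray_polygon_hit(ax$center, ax$major, v))
  p_min <- rbind(.ray_polygon_hit(ax$center, -ax$minor, v),
                 .ray_polygon_hit(ax$center, ax$minor, v))
  O <- (colMeans(p_maj) + colMeans(p_min)) / 2
  a <- sqrt(sum((p_maj[2, ] - p_maj[1, ])^2)) / 2 - inset[1]
  b <- sqrt(sum((p_min[2, ] - p_min[1, ])^2)) / 2 - inset[2]
  pos <- matrix(0, nrow_cells * ncol_cells, 2)
  idx <- 1L
  for (r in seq_len(nrow_cells)) {
    fr <- (2 * r - 1) / (2 * nrow_cells) * 2 - 1
    for (cl in seq_len(ncol_cells)) {
      fc <- (2 * cl - 1) / (2 * ncol_cells) * 2 - 1
      pos[idx, ] <- O + ax$major * (a * fc) + ax$minor * (b * fr)
      idx <- idx + 1L
    }
  }
  list(positions = pos, axes = ax, half_extent = c(a, b),
       crossings = rbind(p_maj, p_min))
}

#' Step 5: sampling-grid placement
#'
#' Principal component analysis of each reference contour gives its axes;
#' the four crossing points of the axes with the contour define the local
#' frame in which the 6 x 18 cell centers are placed. Target positions come
#' from the detected patch contour centers; if those are unavailable the
#' fallback places four equally spaced positions on the midline between the
#' two reference centers, oriented by their mean major-axis slope.
#'
#' @param layout A `scene_layout` from [label_contours()].
#' @param cfg A [detection_config()].
#' @return The layout with `upper_grid`, `lower_grid` (108 x 2 each),
#'   `target_positions` (4 x 2) and per-rectangle axis diagnostics added.
#' @export
place_sampling_grid <- function(layout, cfg = detection_config()) {
  stopifnot(inherits(layout, "scene_layout"))
  up <- .reference_grid_positions(layout$upper_reference,
                                  inset = cfg$frame_inset)
  lo <- .reference_grid_positions(layout$lower_reference,
                                  inset = cfg$frame_inset)
  if (length(layout$targets) == 4L) {
    tp <- t(vapply(layout$targets, `[[`, numeric(2), "centroid"))
  } else {
    axis <- up$axes$major + lo$axes$major
    axis <- axis / sqrt(sum(axis^2))
    mid <- (up$axes$center + lo$axes$center) / 2
    spacing <- (up$half_extent[1] + lo$half_extent[1]) / 6
    tp <- t(vapply(c(-1.5, -0.5, 0.5, 1.5),
                   function(f) mid + axis * (f * spacing), numeric(2)))
  }
  dimn <- layout$image_dim
  all_pos <- rbind(up$positions, lo$positions, tp)
  if (any(all_pos[, 1] < 0) || any(all_pos[, 1] > dimn[2] - 1) ||
      any(all_pos[, 2] < 0) || any(all_pos[, 2] > dimn[1] - 1))
    .detection_error("sampling positions fall outside the image",
                     "positions-in-bounds")
  layout$upper_grid <- up$positions
  layout$lower_grid <- lo$positions
  layout$target_positions <- tp
  layout$upper_axes <- up$axes
  layout$lower_axes <- lo$axes
  layout
}

#' Step 6: color retrieval
#'
#' Samples every grid and patch position as the mean over a square window
#' (side `2 * sample_window + 1`) in linear RGB, converted to u'v'. Windows
#' that cross the image boundary are clipped with a warning.
#'
#' @param img The capture image (unfiltered or simplified).
#' @param layout A `scene_layout` with sampling positions.
#' @param cfg A [detection_config()].
#' @return List with `reference` (216 x 2 u'v', upper rows 1-6 then lower
#'   rows 7-12) and `target` (4 x 2).
#' @export
retrieve_colors <- function(img, layout, cfg = detection_config()) {
  .check_image(img)
  stopifnot(inherits(layout, "scene_layout"),
            !is.null(layout$upper_grid))
  h <- dim(img)[1]; w <- dim(img)[2]
  s <- cfg$sample_window
  clipped <- FALSE
  sample_one <- function(pos) {
    x <- round(pos[1]); y <- round(pos[2])
    x0 <- x - s; x1 <- x + s; y0 <- y - s; y1 <- y + s
    if (x0 < 0 || y0 < 0 || x1 > w - 1 || y1 > h - 1) {
      clipped <<- TRUE
      x0 <- max(x0, 0); y0 <- max(y0, 0)
      x1 <- min(x1, w - 1); y1 <- min(y1, h - 1)
    }
    px <- cbind(as.vector(img[(y0:y1) + 1, (x0:x1) + 1, 1]),
                as.vector(img[(y0:y1) + 1, (x0:x1) + 1, 2]),
                as.vector(img[(y0:y1) + 1, (x0:x1) + 1, 3]))
    average_patch_color(px)
  }
  ref <- rbind(t(apply(layout$upper_grid, 1, sample_one)),
               t(apply(layout$lower_grid, 1, sample_one)))
  tgt <- t(apply(layout$target_positions, 1, sample_one))
  if (clipped)
    warning("sampling window(s) clipped at the image boundary")
  colnames(ref) <- colnames(tgt) <- c("u", "v")
  list(reference = ref, target = tgt)
}

#' Run the full six-step color retrieving algorithm
#'
#' @param img Capture image array.
#' @param cfg A [detection_config()].
#' @return List with `layout` (a `scene_layout` including sampling
#'   positions) and `colors` (as returned by [retrieve_colors()]).
#' @export
detect_scene <- function(img, cfg = detection_config()) {
  simplified <- simplify_image(img, cfg)
  edges <- detect_edges(simplified, cfg)
  contours <- extract_initial_contours(edges, cfg)
  layout <- label_contours(contours, cfg, image_dim = dim(img)[1:2])
  layout <- place_sampling_grid(layout, cfg)
  colors <- retrieve_colors(simplified, layout, cfg)
  list(layout = layout, colors = colors)
}

#' Capture a scene image into a measurement object
#'
#' Convenience wrapper: [detect_scene()] then [measurement_capture()].
#'
#' @inheritParams detect_scene
#' @return A `measurement_capture`.
#' @export
capture_from_image <- function(img, cfg = detection_config()) {
  d <- detect_scene(img, cfg)
  measurement_capture(d$colors$reference, d$colors$target)
}

#' Draw a detection overlay
#'
#' Paints contour outlines, principal axes and sampling positions onto a
#' copy of the image for visual inspection of the detection result.
#'
#' @param img Capture image array.
#' @param layout A `scene_layout` with sampling positions.
#' @return Image array with the overlay drawn.
#' @export
detection_overlay <- function(img, layout) {
  .check_image(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  put <- function(im, x, y, rgb) {
    ok <- x >= 0 & x <= w - 1 & y >= 0 & y <= h - 1
    x <- round(x[ok]); y <- round(y[ok])
    for (ch in 1:3) im[cbind(y + 1, x + 1, ch)] <- rgb[ch]
    im
  }
  draw_poly <- function(im, v, rgb) {
    n <- nrow(v)
    for (i in seq_len(n)) {
      a <- v[i, ]; b <- v[i %% n + 1, ]
      t <- seq(0, 1, length.out = ceiling(sqrt(sum((b - a)^2))) + 1)
      im <- put(im, a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]), rgb)
    }
    im
  }
  out <- img
  cts <- c(list(layout$upper_reference, layout$lower_reference),
           layout$targets)
  for (ct in cts) out <- draw_poly(out, ct$vertices, c(255, 0, 0))
  pos <- rbind(layout$upper_grid, layout$lower_grid, layout$target_positions)
  for (d in -2:2) {
    out <- put(out, pos[, 1] + d, pos[, 2], c(0, 255, 0))
    out <- put(out, pos[, 1], pos[, 2] + d, c(0, 255, 0))
  }
  out
}
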