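---
title: "Colorimetric pH readout by chromatic adaptation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colorimetric pH readout by chromatic adaptation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`phstrip` turns a light-box photograph of a wetted four-patch pH indicator
strip into a quantitative pH estimate. This vignette explains the models
the package implements, the tunable parameters and their defaults, what the
synthetic scene generator does and does not emulate, and the numerical
choices a maintainer should know about.

## The measurement problem

A smartphone camera is a poor colorimeter: automatic white balance,
exposure and tone mapping change the recorded colors from capture to
capture in ways the user cannot control. The system addressed here removes
ambient light as a variable with a closed light box and removes the camera
as a variable with *chromatic adaptation against a printed reference*: two
printed rectangles, each a 6 × 18 grid of assorted colors (216 cells in
total), flank the strip in every photograph. Whatever the camera did to the
scene, it did it to the reference cells too; a map fitted from the observed
reference colors back to a stored reference frame can then be applied to
the strip colors.

All color processing happens in CIE 1976 u′v′ chromaticity coordinates

$$u' = \frac{4X}{X + 15Y + 3Z}, \qquad v' = \frac{9Y}{X + 15Y + 3Z},$$

which are intensity-invariant (a uniform brightness change cancels in the
ratios) and approximately perceptually uniform. Camera pixels are assumed
sRGB-encoded (IEC 61966-2-1, D65 white), the default for smartphone output;
the sRGB transfer function is decoded before averaging pixels, because
chromaticity is a ratio of linear quantities. Both conventions are
configurable at the API level but these defaults are used throughout.

## Chromatic adaptation model

The adaptation map \(F\) from a source chromaticity \((u_s, v_s)\) to a
destination \((u_d, v_d)\) is a third-order bivariate polynomial with 20
parameters — one 10-coefficient regression per output channel over the
shared monomial basis

$$[\,u,\; v,\; 1,\; u^2,\; v^2,\; uv,\; u^3,\; v^3,\; u^2v,\; uv^2\,].$$

The basis order is fixed and serialized with the model so stored
coefficients are comparable across implementations. The two channels are
fitted independently: the model is written as two separate regressions and
nothing couples them. The identity map is exactly representable
(`identity_color_model()`), which matters below.

Each fit uses the 216 correspondences between a capture's reference colors
and the stored frame. To resist outliers (saturated or specular cells), the
fit minimizes the sum of *absolute* residuals, solved by iteratively
reweighted least squares: weights start at 1, and after each weighted
least-squares solve are reset to \(w_i = 1 / \max(\delta, |r_i|)\) with
\(\delta = 0.01\) and exactly 20 iterations. The iteration count is fixed
(no convergence test) so fits are bit-reproducible; an optional early-stop
tolerance exists but is off by default. The weighted solves use a QR
least-squares factorization of the \(\sqrt{w}\)-scaled system rather than
forming \((X^TWX)^{-1}\); the fixed point is the same, the conditioning is
better. A rank-deficient design (reference colors that do not span the
basis, e.g. all cells the same color) raises an explicit error.

Two remarks on \(\delta\). First, it caps the weight any single point can
attain, so for data whose residuals are mostly below \(\delta\) the fit
behaves like ordinary least squares; with 216 well-spread cells this is
harmless. Second, when the IRLS solver is compared against the exact
least-absolute-deviation minimum (found by enumeration on reduced
3-parameter instances — an LAD optimum interpolates at least as many points
as there are parameters), the test instances use \(\delta\) well below
their residual scale, otherwise the clamp, not the solver, dominates the
comparison. The production default stays at 0.01.

## Calibration

Calibration replaces pH buffer solutions with the manufacturer's printed
comparison chart, cut into its 15 single-pH pieces. Each piece is
photographed in the light box (15 captures, integer pH 0–14). The pH 7
capture is the *pivot*: its 216 reference colors define the common frame.
For every index \(P\) a model \(F_P\) is fitted from that capture's
reference colors to the pivot's and applied to the capture's four strip
patch colors. The pivot capture goes through its own fitted (near-identity)
model rather than being copied, so all 15 are processed uniformly; the
difference is bounded by the fit residual, which is at machine-precision
level for the exact-identity case.

The 15 calibrated colors per patch are then interpolated to a 0.1-pH
resolution curve by minimizing

$$E(f) = \sum_{P=0}^{14} \lVert c_P - f(P)\rVert^2
        + \lambda \int f''(x)^2\,dx .$$

The penalty is the one-dimensional thin-plate energy, whose minimizer over
this class is the natural cubic smoothing spline, and the squared norm
separates over the u′ and v′ coordinates, so the vector problem is solved
exactly as two scalar smoothing splines with knots at 0–14. Note the
convention: \(\lambda\) multiplies the raw curvature integral and the error
term is **not** divided by the number of points. Library smoothers
normalize differently (`stats::smooth.spline` rescales both terms), which
is why the Reinsch/Green–Silverman construction is implemented directly —
at 15 knots the cost is negligible.

The default \(\lambda = 3/7\) encodes a 7:3 weighting intent between data
fidelity and smoothness; the package treats it simply as the default value
and logs the *realized* energy split per patch in the calibration object
(`calib$energy`) rather than enforcing any ratio. \(\lambda = 0\)
interpolates the knots exactly; \(\lambda \to \infty\) tends to the
least-squares straight line. The stored calibration product is the pivot's
216 reference colors plus the four 141-point curves, serialized as JSON.

### Numerical note: the large-λ limit

\((I + \lambda K)f = y\) solved directly loses about
\(\lambda \cdot \varepsilon_{mach}\) of absolute accuracy, visible already
at \(\lambda = 10^{12}\). The solver therefore diagonalizes the roughness
matrix \(K\) once (15 × 15, symmetric PSD) and clamps numerically-zero
eigenvalues to exactly zero; the straight-line limit (the null space of
\(K\)) is then reproduced to machine precision for any \(\lambda\), and
moderate \(\lambda\) agrees with the direct solve to rounding error. A
discretized quadratic-program minimizer of the energy on a 0.005-pH grid
serves as the independent oracle in the tests.

## Measurement and best matching

A measurement capture is processed the same way: fit \(F_M\) from its
reference colors to the stored pivot frame, apply it to the four raw patch
colors, then scan the calibrated curves. The estimate is

$$\hat p = \arg\min_{p \in \{0.0, 0.1, \dots, 14.0\}}
  \sum_{k=1}^{4} \lVert \tilde m_k - c_{p,k} \rVert_1 ,$$

where the 1-norm of a u′v′ pair is \(|\Delta u'| + |\Delta v'|\),
consistent with the L1 objective of the adaptation fit. Matching against
all four patches jointly disambiguates the non-monotone single-patch
curves; no analytic inverse (linear or curve fit per patch) is ever formed.
Exact cost ties break toward the lowest pH — a deterministic, documented
rule for a measure-zero event. The full cost profile over the grid is
returned for diagnostics, and an optional parabolic sub-grid refinement is
available but off by default: the estimate of record lives on the 0.1 grid.

Replicate readings are summarized as the mean absolute deviation from the
sample's reference pH and the **population** (divisor *n*) standard
deviation of the estimates, both rounded *half-up* to two decimals.
Estimates and reference values carry at most two decimals, so the
statistics are computed exactly in integer hundredths before rounding;
floating-point `round()` half-to-even would mis-round exact halves such as
0.125 → 0.13. The bundled `buffer_replicates()` table of four-capture
readings on three handsets validates this convention; one of its 24 rows
(handset B, pH 6.0 buffered sample) prints 0.07 where the exact mean error
is 0.075, while another row with the same exact mean prints 0.08 — no
deterministic rounding satisfies both, so that single printed cell is
treated as a typo and the corresponding acceptance check is expected to
flag exactly that cell.

## Automatic color retrieval

Captures are located, not assumed: the strip and reference positions move
between photographs. Six steps:

1. **Simplification.** Channel-wise median filter (default 5 px,
   replicated borders), implemented with the constant-time-per-pixel
   histogram algorithm.
2. **Edges.** Canny detection on the luma channel (Sobel gradients,
   non-maximum suppression, hysteresis at 40/120 on the 8-bit gradient
   scale) followed by morphological closing with a 5 × 5 square. The
   closing both merges the twin edge chains on either side of a printed
   stroke and bridges the gaps non-maximum suppression leaves at corners
   and along staircased diagonals — gaps that exceed one pixel, which is
   why the element is 5 and not 3.
3. **Initial contours.** Every 8-connected edge component is traced
   (Moore neighbor tracing) and reduced to a quadrilateral: the convex
   hull is taken (removing inward spikes where the trace dives through a
   chain gap), near-collinear hull vertices are merged (rasterized
   straight sides stair-step into many short hull edges), and the four
   longest remaining edges are intersected as side lines. This recovers
   corners that rasterization chamfers *off* the hull, which inscribed
   approximations (Douglas–Peucker, vertex decimation) systematically
   miss. Three filters reject non-rectangles: the four chosen sides must
   cover ≥ 70% of the hull perimeter (a round blob's four longest chords
   cover ~4/n), the traced boundary must adhere to the quadrilateral
   (≥ 60% of trace points within 8 px of its perimeter — a star spends
   most of its boundary deep inside its hull), and the area must exceed
   5 × 10⁻⁴ of the image.
4. **Labeling.** The strip lies along the image's horizontal midline with
   the reference rectangles above and below, so the "center line"
   separating the two contour classes is horizontal: reference candidates
   have side-length aspect ratio > 3.5 (the printed reference is
   30 × 8 mm, aspect 3.75; side lengths, not bounding boxes, so rotation
   does not inflate the ratio) and centers outside a band of 0.15 × image
   height about the midline; topmost → upper, bottommost → lower. Target
   candidates are square-like (aspect ≤ 1.3) inside the band; the largest
   cluster of areas within ±30% of its median must contain exactly four,
   ordered along the strip axis anchored at the end nearer the image's
   left edge. Nested duplicates (inner/outer edge of one printed border)
   are removed by containment, keeping the outer. Any violated constraint
   raises a structured error naming the constraint, which the CLI turns
   into a re-capture prompt.
5. **Grid placement.** Principal component analysis of each reference
   quadrilateral's vertices gives its axes; the four crossing points of
   the axes with the contour define the local frame, and the 6 × 18 cell
   centers are placed by bilinear interpolation (columns along the major
   axis, rows along the minor). Axis orientation is disambiguated
   deterministically (major toward +x, minor toward +y after rotation
   normalization), a convention calibration and measurement share.
   Target positions prefer the detected patch centers and fall back to
   the reference midline construction when patch contours are missing.
6. **Retrieval.** Each color is the mean over a 7 × 7 window in linear
   RGB, converted to u′v′; boundary-crossing windows are clipped with a
   warning.

None of the kernel sizes or thresholds are dictated by the printed chart;
all live in `detection_config()` and the defaults were fixed once against
the synthetic fixture suite. On that suite, layout detection succeeds on
100/100 randomized poses and the retrieved colors match the rendered
ground truth to well below 10⁻² in u′v′ (exactly, in the noise-free case);
grid positions land within about one pixel of the true cell centers.

## The synthetic world

Real captures require the physical light box, so the package ships a
renderer that *is* a first-class module: it draws the canonical scene —
two 6 × 18 reference grids (cells 30 × 24 px, black 4 px strokes, the
rectangle at the printed 3.75 aspect) above and below four 70 px strip
patches on a 960 × 720 canvas — and applies a camera model: pose jitter
(translation, rotation, scale about the image center), a chromaticity
distortion, brightness gain, and additive Gaussian sensor noise, returning
the image together with ground-truth positions and colors.

The palette is a 12 × 18 lattice in u′v′ (spacing 0.011, seeded jitter
±4 × 10⁻⁴), which keeps every pair of reference colors more than 0.01
apart — enough spread to condition the 10-parameter fits — and stays
inside the sRGB gamut at the render luminance Y = 0.22. Luminance is a
compromise: higher Y quantizes chromaticity more finely but pushes the
palette's saturated corner cells out of gamut (already at Y = 0.3 some
cells clip). At Y = 0.22 the 8-bit quantization floor is about
1.2 × 10⁻³ in u′v′, the resolution limit all exactness tests are read
against.

The strip model gives each patch a smooth non-monotone trajectory: anchors
at integer pH from low-frequency sinusoids (u′ amplitude 0.06, v′
amplitude 0.04, frequencies 0.35–0.55 rad/pH — roughly one broad arc over
the range, qualitatively like printed comparison charts), joined by
natural cubic spline interpolation. Single patches revisit colors; the
four-patch joint match is what makes the argmin unique.

The default camera distortion is drawn *within the polynomial family*
(all 20 coefficients perturbed uniformly within ±0.05 of the identity),
which separates "can the pipeline invert what its model can represent"
from robustness to model mismatch; an out-of-family mode (3 × 3 mixing
matrix plus per-channel gamma in linear RGB) exists for the latter.
Large in-family shifts can push edge cells past the gamut boundary, where
rendering clips them — those cells become exactly the kind of outlier the
L1 fit is there to absorb.

What a green synthetic suite does **not** establish: performance under
non-uniform illumination inside a real light box, JPEG compression,
perspective (the renderer applies similarity transforms only, no
homography), chemical effects (a buffer whose chemistry biases the strip
color reads consistently wrong regardless of color processing), or the
color accuracy of a real printed chart. These are physical error sources
outside computational scope.

## Closed-loop behavior and accuracy

With an identity camera and no noise, the full pipeline — render 15
charts, detect, calibrate, render a measurement scene, detect, measure —
returns the true pH exactly on the 0.1 grid: adaptation fits are exact
(the identity is in the family), and the residual error (quantization
~10⁻³ plus smoothing bias, both smooth in pH) is an order of magnitude
below the per-0.1-step cost increment of the four-patch match. With
per-capture random in-family distortions and sensor noise σ = 2 the mean
absolute error over 50 scenes is ~0.01–0.04 pH across seeds, against an
acceptance bound of 0.25 — the headline accuracy the method reports on
real buffer solutions, transplanted to the synthetic world.

## Known limitations

- PNG (and plain-text PPM) input only; camera RAW and ICC profiles are out
  of scope, and JPEG decoding depends on an optional reader not required
  by the package.
- The detector expects the canonical topology (two elongated references
  flanking a four-patch strip) and similarity-transform poses within
  roughly ±10°, ±20 px, ±10% scale; perspective rectification is not
  implemented.
- Grid dimensions other than 6 × 18 are constants in the code paths, not a
  tested configuration surface.
- The 0.1-pH grid bounds the resolution of the estimate of record;
  sub-grid refinement exists but is deliberately off by default.
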