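// Low-level raster operations backing the automatic color retrieving
// algorithm: median filtering, Canny edge detection, binary morphology and
// connected-component outer-boundary tracing. Matrices are R numeric
// matrices indexed [row, col] with 0-based C loops; boundary coordinates are
// returned 0-based as (x = col, y = row).

#include <Rcpp.h>
#include <algorithm>
#include <queue>
#include <vector>
#include <cmath>

using namespace Rcpp;

// 8-bit median filter with replicated borders, using per-column histograms
// updated incrementally (Huang's constant-time-per-pixel algorithm).
// [[Rcpp::export]]
NumericMatrix cpp_median_filter(const NumericMatrix& img, int k) {
  if (k < 1 || k % 2 == 0) stop("median kernel must be odd and positive");
  int h = img.nrow(), w = img.ncol(), r = k / 2;
  if (k > h || k > w) stop("median kernel larger than image");
  // quantize to 8-bit bins (inputs are 8-bit images)
  std::vector<unsigned char> q((size_t)h * w);
  for (int x = 0; x < w; ++x)
    for (int y = 0; y < h; ++y) {
      double v = img(y, x);
      q[(size_t)x * h + y] =
        (unsigned char)std::min(255.0, std::max(0.0, v + 0.5));
    }
  NumericMatrix out(h, w);
  std::vector<int> colhist((size_t)w * 256, 0);  // per-column histograms
  int target = (k * k) / 2 + 1;                  // rank of the median
  // initialize column histograms with rows [-r, r] (replicated)
  for (int x = 0; x < w; ++x)
    for (int dy = -r; dy <= r; ++dy) {
      int yy = std::min(std::max(dy, 0), h - 1);
      ++colhist[(size_t)x * 256 + q[(size_t)x * h + yy]];
    }
  std::vector<int> hist(256);
  for (int y = 0; y < h; ++y) {
    if (y > 0) {  // roll column histograms one row down
      int y_out = std::min(std::max(y - 1 - r, 0), h - 1);
      int y_in = std::min(std::max(y + r, 0), h - 1);
      for (int x = 0; x < w; ++x) {
        --colhist[(size_t)x * 256 + q[(size_t)x * h + y_out]];
        ++colhist[(size_t)x * 256 + q[(size_t)x * h + y_in]];
      }
    }
    // kernel histogram for x = 0 (replicated left border)
    std::fill(hist.begin(), hist.end(), 0);
    for (int dx = -r; dx <= r; ++dx) {
      int xx = std::min(std::max(dx, 0), w - 1);
      const int* ch = &colhist[(size_t)xx * 256];
      for (int b = 0; b < 256; ++b) hist[b] += ch[b];
    }
    for (int x = 0; x < w; ++x) {
      if (x > 0) {
        int x_out = std::min(std::max(x - 1 - r, 0), w - 1);
        int x_in = std::min(std::max(x + r, 0), w - 1);
        const int* co = &colhist[(size_t)x_out * 256];
        const int* ci = &colhist[(size_t)x_in * 256];
        for (int b = 0; b < 256; ++b) hist[b] += ci[b] - co[b];
      }
      int acc = 0, med = 0;
      for (int b = 0; b < 256; ++b) {
        acc += hist[b];
        if (acc >= target) { med = b; break; }
      }
      out(y, x) = med;
    }
  }
  return out;
}

// Canny edge detector on a (pre-smoothed) grayscale image: Sobel gradients,
// non-maximum suppression along the quantized gradient direction, and
// double-threshold hysteresis (8-connected).
// [[Rcpp::export]]
IntegerMatrix cpp_canny(const NumericMatrix& gray, double low, double high) {
  if (!(low < high)) stop("canny thresholds require low < high");
  int h = gray.nrow(), w = gray.ncol();
  NumericMatrix gx(h, w), gy(h, w), mag(h, w);
  for (int y = 1; y < h - 1; ++y) {
    for (int x = 1; x < w - 1; ++x) {
      double sx =
        -gray(y - 1, x - 1) + gray(y - 1, x + 1)
        - 2 * gray(y, x - 1) + 2 * gray(y, x + 1)
        - gray(y + 1, x - 1) + gray(y + 1, x + 1);
      double sy =
        -gray(y - 1, x - 1) - 2 * gray(y - 1, x) - gray(y - 1, x + 1)
        + gray(y + 1, x - 1) + 2 * gray(y + 1, x) + gray(y + 1, x + 1);
      gx(y, x) = sx;
      gy(y, x) = sy;
      mag(y, x) = std::sqrt(sx * sx + sy * sy);
    }
  }
  IntegerMatrix edge(h, w);
  // non-maximum suppression: compare against the two neighbors along the
  // gradient direction quantized to 0, 45, 90, 135 degrees
  for (int y = 1; y < h - 1; ++y) {
    for (int x = 1; x < w - 1; ++x) {
      double m = mag(y, x);
      if (m < low) continue;
      double ang = std::atan2(gy(y, x), gx(y, x)) * 180.0 / M_PI;
      if (ang < 0) ang += 180.0;
      double m1, m2;
      if (ang < 22.5 || ang >= 157.5) {        // horizontal gradient
        m1 = mag(y, x - 1); m2 = mag(y, x + 1);
      } else if (ang < 67.5) {                 // diagonal /
        m1 = mag(y - 1, x + 1); m2 = mag(y + 1, x - 1);
      } else if (ang < 112.5) {                // vertical gradient
        m1 = mag(y - 1, x); m2 = mag(y + 1, x);
      } else {                                 // diagonal backslash
        m1 = mag(y - 1, x - 1); m2 = mag(y + 1, x + 1);
      }
      if (m >= m1 && m >= m2) edge(y, x) = (m >= high) ? 2 : 1;
    }
  }
  // hysteresis: keep weak edges 8-connected to a strong edge
  std::queue<std::pair<int, int> > q;
  for (int y = 0; y < h; ++y)
    for (int x = 0; x < w; ++x)
      if (edge(y, x) == 2) q.push(std::make_pair(y, x));
  while (!q.empty()) {
    std::pair<int, int> p = q.front(); q.pop();
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int yy = p.first + dy, xx = p.second + dx;
        if (yy < 0 || yy >= h || xx < 0 || xx >= w) continue;
        if (edge(yy, xx) == 1) {
          edge(yy, xx) = 2;
          q.push(std::make_pair(yy, xx));
        }
      }
  }
  IntegerMatrix out(h, w);
  for (int y = 0; y < h; ++y)
    for (int x = 0; x < w; ++x)
      out(y, x) = edge(y, x) == 2 ? 1 : 0;
  return out;
}

static IntegerMatrix dilate_or_erode(const IntegerMatrix& bin, int r,
                                     bool dilate) {
  int h = bin.nrow(), w = bin.ncol();
  IntegerMatrix out(h, w);
  for (int y = 0; y < h; ++y) {
    for (int x = 0; x < w; ++x) {
      int v = dilate ? 0 : 1;
      for (int dy = -r; dy <= r && (dilate ? v == 0 : v == 1); ++dy) {
        int yy = y + dy;
        for (int dx = -r; dx <= r; ++dx) {
          int xx = x + dx;
          int px;
          if (yy < 0 || yy >= h || xx < 0 || xx >= w)
            px = 0;  // outside image counts as background
          else
            px = bin(yy, xx);
          if (dilate && px == 1) { v = 1; break; }
          if (!dilate && px == 0) { v = 0; break; }
        }
      }
      out(y, x) = v;
    }
  }
  return out;
}

// Morphological closing (dilate then erode) with a square structuring
// element of side 2*radius+1.
// [[Rcpp::export]]
IntegerMatrix cpp_binary_close(const IntegerMatrix& bin, int radius) {
  if (radius < 0) stop("radius must be >= 0");
  if (radius == 0) return clone(bin);
  return dilate_or_erode(dilate_or_erode(bin, radius, true), radius, false);
}

// Outer boundaries of all 8-connected foreground components, by
// Moore-neighbor tracing from the first (raster-order) pixel of each
// component. Returns a list of n x 2 matrices of 0-based (x, y) boundary
// coordinates, ordered around the component.
// [[Rcpp::export]]
List cpp_component_boundaries(const IntegerMatrix& bin, int min_pixels) {
  int h = bin.nrow(), w = bin.ncol();
  IntegerMatrix label(h, w);
  List out;
  int next_label = 0;
  // clockwise neighbor order starting at west
  const int DX[8] = { -1, -1, 0, 1, 1, 1, 0, -1 };
  const int DY[8] = { 0, -1, -1, -1, 0, 1, 1, 1 };
  std::vector<int> stack_y, stack_x;
  for (int y0 = 0; y0 < h; ++y0) {
    for (int x0 = 0; x0 < w; ++x0) {
      if (bin(y0, x0) != 1 || label(y0, x0) != 0) continue;
      // flood fill the component to label and count it
      ++next_label;
      int count = 0;
      stack_y.clear(); stack_x.clear();
      stack_y.push_back(y0); stack_x.push_back(x0);
      label(y0, x0) = next_label;
      while (!stack_y.empty()) {
        int y = stack_y.back(), x = stack_x.back();
        stack_y.pop_back(); stack_x.pop_back();
        ++count;
        for (int d = 0; d < 8; ++d) {
          int yy = y + DY[d], xx = x + DX[d];
          if (yy < 0 || yy >= h || xx < 0 || xx >= w) continue;
          if (bin(yy, xx) == 1 && label(yy, xx) == 0) {
            label(yy, xx) = next_label;
            stack_y.push_back(yy); stack_x.push_back(xx);
          }
        }
      }
      if (count < min_pixels) continue;
      // Moore tracing from (y0, x0); backtrack starts at west neighbor
      std::vector<int> bx, by;
      int py = y0, px = x0;
      int backdir = 0;  // direction from p to previous background (west)
      bx.push_back(px); by.push_back(py);
      int start_y = py, start_x = px, start_next = -1;
      for (long it = 0; it < (long)8 * h * w; ++it) {
        int found = -1;
        for (int s = 1; s <= 8; ++s) {
          int d = (backdir + s) % 8;  // clockwise from backtrack
          int yy = py + DY[d], xx = px + DX[d];
          if (yy >= 0 && yy < h && xx >= 0 && xx < w &&
              label(yy, xx) == next_label) {
            found = d;
            break;
          }
        }
        if (found < 0) break;  // isolated pixel
        int ny = py + DY[found], nx = px + DX[found];
        if (it == 0) start_next = found;
        else if (py == start_y && px == start_x && found == start_next)
          break;  // Jacob's stopping criterion
        // radial sweep: next scan starts just clockwise of the direction
        // pointing back at the pixel we came from
        backdir = (found + 4) % 8;
        py = ny; px = nx;
        if (!(py == start_y && px == start_x)) {
          bx.push_back(px); by.push_back(py);
        }
      }
      IntegerMatrix b(bx.size(), 2);
      for (size_t i = 0; i < bx.size(); ++i) {
        b(i, 0) = bx[i];
        b(i, 1) = by[i];
      }
      out.push_back(List::create(_["xy"] = b, _["pixels"] = count));
    }
  }
  return out;
}
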