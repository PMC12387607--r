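// Canny edge detection and binary morphology primitives.
//
// Conventions (fixed so results are bit-stable):
//  - boundary handling for smoothing/gradients: symmetric (mirror) padding;
//  - Sobel 3x3 gradients; non-maximum suppression with the gradient
//    direction quantized to 4 bins, ties kept (>=);
//  - hysteresis thresholds are fractions of the maximum gradient magnitude,
//    linking is 8-connected;
//  - erosion uses the set definition (pixels outside the image are
//    background), dilation ORs shifted copies of the foreground;
//  - hole filling and component labelling are 8-connected.
#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

static inline int mirror(int i, int n) {
  // symmetric padding: -1 -> 0, -2 -> 1, n -> n-1, ...
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// separable Gaussian smoothing, radius = max(1, ceil(3*sigma))
// [[Rcpp::export]]
NumericMatrix cpp_gauss_smooth(NumericMatrix x, double sigma) {
  int H = x.nrow(), W = x.ncol();
  int rad = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> kern(2 * rad + 1);
  double s = 0;
  for (int i = -rad; i <= rad; ++i) {
    kern[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += kern[i + rad];
  }
  for (double& k : kern) k /= s;
  NumericMatrix tmp(H, W), out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double a = 0;
      for (int i = -rad; i <= rad; ++i) a += kern[i + rad] * x(mirror(r + i, H), c);
      tmp(r, c) = a;
    }
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double a = 0;
      for (int i = -rad; i <= rad; ++i) a += kern[i + rad] * tmp(r, mirror(c + i, W));
      out(r, c) = a;
    }
  return out;
}

// generic odd-kernel 2D correlation with symmetric padding (per channel use)
// [[Rcpp::export]]
NumericMatrix cpp_filter2_reflect(NumericMatrix x, NumericMatrix kern) {
  int H = x.nrow(), W = x.ncol();
  int kh = kern.nrow(), kw = kern.ncol();
  if (kh % 2 == 0 || kw % 2 == 0) stop("kernel dims must be odd");
  int rh = kh / 2, rw = kw / 2;
  NumericMatrix out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double a = 0;
      for (int j = -rw; j <= rw; ++j)
        for (int i = -rh; i <= rh; ++i)
          a += kern(i + rh, j + rw) * x(mirror(r + i, H), mirror(c + j, W));
      out(r, c) = a;
    }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_canny(NumericMatrix lum, double sigma, double low_frac,
                        double high_frac) {
  int H = lum.nrow(), W = lum.ncol();
  NumericMatrix sm = cpp_gauss_smooth(lum, sigma);
  NumericMatrix gx(H, W), gy(H, W), mag(H, W);
  // Sobel: gx = horizontal derivative (along columns), gy = vertical
  double maxmag = 0;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double a = 0, b = 0;
      for (int i = -1; i <= 1; ++i)
        for (int j = -1; j <= 1; ++j) {
          double v = sm(mirror(r + i, H), mirror(c + j, W));
          int wx = (j == 0) ? 0 : j * (i == 0 ? 2 : 1);
          int wy = (i == 0) ? 0 : i * (j == 0 ? 2 : 1);
          a += wx * v;
          b += wy * v;
        }
      gx(r, c) = a; gy(r, c) = b;
      mag(r, c) = std::sqrt(a * a + b * b);
      if (mag(r, c) > maxmag) maxmag = mag(r, c);
    }
  IntegerMatrix out(H, W);
  // gradients below this absolute floor (intensity units) are numerical
  // noise from kernel normalization, not structure — flat images stay empty
  if (maxmag <= 1e-6) return out;
  double hi = high_frac * maxmag, lo = low_frac * maxmag;

  // non-maximum suppression, 4 quantized directions
  IntegerMatrix keep(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double m = mag(r, c);
      if (m < lo) continue;
      double th = std::atan2(gy(r, c), gx(r, c));
      if (th < 0) th += M_PI;
      int dr, dc;
      if (th < M_PI / 8 || th >= 7 * M_PI / 8) { dr = 0; dc = 1; }
      else if (th < 3 * M_PI / 8) { dr = 1; dc = 1; }
      else if (th < 5 * M_PI / 8) { dr = 1; dc = 0; }
      else { dr = 1; dc = -1; }
      double m1 = (r + dr >= 0 && r + dr < H && c + dc >= 0 && c + dc < W) ? mag(r + dr, c + dc) : 0;
      double m2 = (r - dr >= 0 && r - dr < H && c - dc >= 0 && c - dc < W) ? mag(r - dr, c - dc) : 0;
      if (m >= m1 && m >= m2) keep(r, c) = 1;
    }

  // hysteresis: BFS from strong pixels through weak candidates, 8-connected
  std::queue<std::pair<int, int>> q;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      if (keep(r, c) && mag(r, c) >= hi) { out(r, c) = 1; q.push({r, c}); }
  while (!q.empty()) {
    auto [r, c] = q.front(); q.pop();
    for (int dc = -1; dc <= 1; ++dc)
      for (int dr = -1; dr <= 1; ++dr) {
        int rr = r + dr, cc = c + dc;
        if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
        if (!out(rr, cc) && keep(rr, cc) && mag(rr, cc) >= lo) {
          out(rr, cc) = 1;
          q.push({rr, cc});
        }
      }
  }
  return out;
}

// ---- binary morphology -----------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_dilate(IntegerMatrix mask, LogicalMatrix se) {
  int H = mask.nrow(), W = mask.ncol();
  int rh = se.nrow() / 2, rw = se.ncol() / 2;
  IntegerMatrix out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c)) continue;
      for (int j = -rw; j <= rw; ++j)
        for (int i = -rh; i <= rh; ++i) {
          if (!se(i + rh, j + rw)) continue;
          int rr = r + i, cc = c + j;
          if (rr >= 0 && rr < H && cc >= 0 && cc < W) out(rr, cc) = 1;
        }
    }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_erode(IntegerMatrix mask, LogicalMatrix se) {
  int H = mask.nrow(), W = mask.ncol();
  int rh = se.nrow() / 2, rw = se.ncol() / 2;
  IntegerMatrix out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      bool all = true;
      for (int j = -rw; j <= rw && all; ++j)
        for (int i = -rh; i <= rh && all; ++i) {
          if (!se(i + rh, j + rw)) continue;
          int rr = r + i, cc = c + j;
          if (rr < 0 || rr >= H || cc < 0 || cc >= W || !mask(rr, cc)) all = false;
        }
      out(r, c) = all ? 1 : 0;
    }
  return out;
}

// fill holes: background regions (8-connected) not reachable from the border
// become foreground
// [[Rcpp::export]]
IntegerMatrix cpp_fill_holes(IntegerMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix reach(H, W);
  std::queue<std::pair<int, int>> q;
  for (int r = 0; r < H; ++r) {
    for (int c : {0, W - 1})
      if (!mask(r, c) && !reach(r, c)) { reach(r, c) = 1; q.push({r, c}); }
  }
  for (int c = 0; c < W; ++c) {
    for (int r : {0, H - 1})
      if (!mask(r, c) && !reach(r, c)) { reach(r, c) = 1; q.push({r, c}); }
  }
  while (!q.empty()) {
    auto [r, c] = q.front(); q.pop();
    for (int dc = -1; dc <= 1; ++dc)
      for (int dr = -1; dr <= 1; ++dr) {
        int rr = r + dr, cc = c + dc;
        if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
        if (!mask(rr, cc) && !reach(rr, cc)) { reach(rr, cc) = 1; q.push({rr, cc}); }
      }
  }
  IntegerMatrix out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      out(r, c) = (mask(r, c) || !reach(r, c)) ? 1 : 0;
  return out;
}

// 8-connected component labelling (labels 1..n in scan order)
// [[Rcpp::export]]
IntegerMatrix cpp_label(IntegerMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::queue<std::pair<int, int>> q;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      lab(r, c) = ++next;
      q.push({r, c});
      while (!q.empty()) {
        auto [rr, cc] = q.front(); q.pop();
        for (int dc = -1; dc <= 1; ++dc)
          for (int dr = -1; dr <= 1; ++dr) {
            int r2 = rr + dr, c2 = cc + dc;
            if (r2 < 0 || r2 >= H || c2 < 0 || c2 >= W) continue;
            if (mask(r2, c2) && !lab(r2, c2)) { lab(r2, c2) = next; q.push({r2, c2}); }
          }
      }
    }
  return lab;
}
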