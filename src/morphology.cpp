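// Low-level raster operations for binary cell masks.
// Matrices are R matrices indexed [y, x] (row-major semantics, column-major
// storage); all functions treat pixels outside the image as background.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const int DY8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DX8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
static const int DY4[4] = {-1, 0, 0, 1};
static const int DX4[4] = {0, -1, 1, 0};

// Connected-component labeling. connectivity: 4 or 8. Labels are assigned
// 1..K in raster-scan order of each component's first pixel.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity) {
  int ny = mask.nrow(), nx = mask.ncol();
  IntegerMatrix lab(ny, nx);
  const int *dy = connectivity == 4 ? DY4 : DY8;
  const int *dx = connectivity == 4 ? DX4 : DX8;
  int nd = connectivity == 4 ? 4 : 8;
  int next = 0;
  std::vector<int> stack;
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      if (!mask(y, x) || lab(y, x)) continue;
      ++next;
      stack.clear();
      stack.push_back(y + x * ny);
      lab(y, x) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int py = p % ny, px = p / ny;
        for (int k = 0; k < nd; ++k) {
          int qy = py + dy[k], qx = px + dx[k];
          if (qy < 0 || qy >= ny || qx < 0 || qx >= nx) continue;
          if (mask(qy, qx) && !lab(qy, qx)) {
            lab(qy, qx) = next;
            stack.push_back(qy + qx * ny);
          }
        }
      }
    }
  }
  return lab;
}

// Binary erosion/dilation with an arbitrary structuring element given as a
// K x 2 matrix of (dy, dx) offsets. Outside the image is background.
// [[Rcpp::export]]
LogicalMatrix cpp_binary_morph(LogicalMatrix mask, IntegerMatrix offsets,
                               bool dilate) {
  int ny = mask.nrow(), nx = mask.ncol(), K = offsets.nrow();
  LogicalMatrix out(ny, nx);
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      if (dilate) {
        bool hit = false;
        for (int k = 0; k < K && !hit; ++k) {
          int qy = y - offsets(k, 0), qx = x - offsets(k, 1);
          if (qy >= 0 && qy < ny && qx >= 0 && qx < nx && mask(qy, qx))
            hit = true;
        }
        out(y, x) = hit;
      } else {
        bool all = true;
        for (int k = 0; k < K && all; ++k) {
          int qy = y + offsets(k, 0), qx = x + offsets(k, 1);
          if (qy < 0 || qy >= ny || qx < 0 || qx >= nx || !mask(qy, qx))
            all = false;
        }
        out(y, x) = all;
      }
    }
  }
  return out;
}

static void edt_1d(const std::vector<double> &f, std::vector<double> &d,
                   int n) {
  // Felzenszwalb & Huttenlocher lower-envelope-of-parabolas transform.
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0; z[0] = -INF; z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    double s;
    while (true) {
      if (f[v[k]] == INF) { // previous parabola absent
        if (k == 0) { v[0] = q; z[0] = -INF; z[1] = INF; goto placed; }
        --k;
        continue;
      }
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
    placed: ;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    if (f[v[0]] == INF) { d[q] = INF; continue; }
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact Euclidean distance transform: distance (in pixels) from each pixel
// to the nearest TRUE pixel. All-FALSE input yields Inf everywhere.
// [[Rcpp::export]]
NumericMatrix cpp_edt(LogicalMatrix mask) {
  int ny = mask.nrow(), nx = mask.ncol();
  const double INF = std::numeric_limits<double>::infinity();
  NumericMatrix g(ny, nx);
  std::vector<double> f(std::max(ny, nx)), d(std::max(ny, nx));
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) f[y] = mask(y, x) ? 0.0 : INF;
    edt_1d(f, d, ny);
    for (int y = 0; y < ny; ++y) g(y, x) = d[y];
  }
  NumericMatrix out(ny, nx);
  for (int y = 0; y < ny; ++y) {
    for (int x = 0; x < nx; ++x) f[x] = g(y, x);
    edt_1d(f, d, nx);
    for (int x = 0; x < nx; ++x) out(y, x) = std::sqrt(d[x]);
  }
  return out;
}

struct WsEntry {
  double elev;
  long order;
  int y, x, label;
};
struct WsCompare {
  bool operator()(const WsEntry &a, const WsEntry &b) const {
    if (a.elev != b.elev) return a.elev > b.elev; // min-heap on elevation
    return a.order > b.order;                     // FIFO tie-break
  }
};

// Seeded watershed by priority flooding restricted to `mask`. Marker pixels
// keep their labels; unreachable mask pixels stay 0.
// [[Rcpp::export]]
IntegerMatrix cpp_watershed(NumericMatrix elevation, IntegerMatrix markers,
                            LogicalMatrix mask) {
  int ny = elevation.nrow(), nx = elevation.ncol();
  IntegerMatrix lab(ny, nx);
  std::priority_queue<WsEntry, std::vector<WsEntry>, WsCompare> pq;
  long counter = 0;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      if (markers(y, x) > 0 && mask(y, x)) {
        lab(y, x) = markers(y, x);
        pq.push(WsEntry{elevation(y, x), counter++, y, x, markers(y, x)});
      }
  while (!pq.empty()) {
    WsEntry e = pq.top(); pq.pop();
    for (int k = 0; k < 8; ++k) {
      int qy = e.y + DY8[k], qx = e.x + DX8[k];
      if (qy < 0 || qy >= ny || qx < 0 || qx >= nx) continue;
      if (!mask(qy, qx) || lab(qy, qx)) continue;
      lab(qy, qx) = e.label;
      pq.push(WsEntry{elevation(qy, qx), counter++, qy, qx, e.label});
    }
  }
  return lab;
}

// Separable convolution with a symmetric 1-D kernel (zero padding).
// [[Rcpp::export]]
NumericMatrix cpp_sepconv(NumericMatrix img, NumericVector kernel) {
  int ny = img.nrow(), nx = img.ncol(), K = kernel.size(), h = K / 2;
  NumericMatrix tmp(ny, nx), out(ny, nx);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      double s = 0;
      for (int k = 0; k < K; ++k) {
        int q = y + k - h;
        if (q >= 0 && q < ny) s += img(q, x) * kernel[k];
      }
      tmp(y, x) = s;
    }
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      double s = 0;
      for (int k = 0; k < K; ++k) {
        int q = x + k - h;
        if (q >= 0 && q < nx) s += tmp(y, q) * kernel[k];
      }
      out(y, x) = s;
    }
  return out;
}

// Total length of the `level` iso-contour of a scalar field, by marching
// squares with linear interpolation. Saddle cells are resolved with the
// cell-centre mean. The field should be zero-padded by the caller so that
// contours close at the image border.
// [[Rcpp::export]]
double cpp_contour_length(NumericMatrix field, double level) {
  int ny = field.nrow(), nx = field.ncol();
  double total = 0.0;
  for (int x = 0; x + 1 < nx; ++x) {
    for (int y = 0; y + 1 < ny; ++y) {
      double a = field(y, x),     b = field(y, x + 1);
      double d = field(y + 1, x), c = field(y + 1, x + 1);
      bool sa = a >= level, sb = b >= level, sc = c >= level, sd = d >= level;
      int idx = (sa ? 1 : 0) | (sb ? 2 : 0) | (sc ? 4 : 0) | (sd ? 8 : 0);
      if (idx == 0 || idx == 15) continue;
      // Edge crossings in cyclic order: top (a-b), right (b-c),
      // bottom (c-d), left (d-a). Coordinates (x', y') in pixel units.
      double px[4], py[4];
      int nc = 0;
      if (sa != sb) { double t = (level - a) / (b - a); px[nc] = x + t;     py[nc] = y;         ++nc; }
      if (sb != sc) { double t = (level - b) / (c - b); px[nc] = x + 1;     py[nc] = y + t;     ++nc; }
      if (sc != sd) { double t = (level - c) / (d - c); px[nc] = x + 1 - t; py[nc] = y + 1;     ++nc; }
      if (sd != sa) { double t = (level - d) / (a - d); px[nc] = x;         py[nc] = y + 1 - t; ++nc; }
      if (nc == 2) {
        total += std::hypot(px[0] - px[1], py[0] - py[1]);
      } else if (nc == 4) {
        double centre = 0.25 * (a + b + c + d);
        // Pairing keeps regions of the same sign as the centre connected.
        if ((centre >= level) == sa) {
          total += std::hypot(px[0] - px[3], py[0] - py[3]);
          total += std::hypot(px[1] - px[2], py[1] - py[2]);
        } else {
          total += std::hypot(px[0] - px[1], py[0] - py[1]);
          total += std::hypot(px[2] - px[3], py[2] - py[3]);
        }
      }
    }
  }
  return total;
}

// Boundary pixels: foreground pixels with at least one 4-neighbour outside
// the foreground (image border counts as background).
// [[Rcpp::export]]
LogicalMatrix cpp_boundary(LogicalMatrix mask) {
  int ny = mask.nrow(), nx = mask.ncol();
  LogicalMatrix out(ny, nx);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      if (!mask(y, x)) continue;
      bool edge = false;
      for (int k = 0; k < 4 && !edge; ++k) {
        int qy = y + DY4[k], qx = x + DX4[k];
        if (qy < 0 || qy >= ny || qx < 0 || qx >= nx || !mask(qy, qx))
          edge = true;
      }
      out(y, x) = edge;
    }
  return out;
}
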