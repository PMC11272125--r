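// Low-level raster operations for nucleus segmentation.
// Matrices are column-major (R layout); coordinates are 0-based (row, col).

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const int DR8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
static const int DR4[4] = {-1, 0, 0, 1};
static const int DC4[4] = {0, -1, 1, 0};

// Connected-component labelling of a binary mask (4- or 8-connectivity),
// labels 1..K in scan order of the first pixel encountered.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int nnb = (connectivity == 4) ? 4 : 8;
  const int* dr = (connectivity == 4) ? DR4 : DR8;
  const int* dc = (connectivity == 4) ? DC4 : DC8;
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.clear();
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int rr = idx % nr, cc = idx / nr;
        for (int k = 0; k < nnb; ++k) {
          int r2 = rr + dr[k], c2 = cc + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  return lab;
}

// 1-d squared-distance transform (Felzenszwalb & Huttenlocher 2004).
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// Exact Euclidean distance transform: distance from each foreground pixel to
// the nearest background pixel (pixels outside the image count as background).
// [[Rcpp::export]]
NumericMatrix cpp_edt(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const double INF = 1e20;
  NumericMatrix d2(nr, nc);
  // pass 1: along columns
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) f[r] = mask(r, c) ? INF : 0.0;
    dt1d(f, d, nr);
    for (int r = 0; r < nr; ++r) d2(r, c) = d[r];
  }
  // pass 2: along rows
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) f[c] = d2(r, c);
    dt1d(f, d, nc);
    for (int c = 0; c < nc; ++c) d2(r, c) = d[c];
  }
  // border pixels are one step from implicit background outside the image
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double v = d2(r, c);
      double bor = std::min(std::min(r + 1, nr - r), std::min(c + 1, nc - c));
      v = std::min(v, bor * bor);
      out(r, c) = std::sqrt(v);
    }
  return out;
}

// Grayscale morphological reconstruction by dilation of `marker` under `mask`
// (marker <= mask pointwise); hybrid raster/queue algorithm (Vincent 1993).
// [[Rcpp::export]]
NumericMatrix cpp_reconstruct(const NumericMatrix& marker,
                              const NumericMatrix& mask) {
  const int nr = marker.nrow(), nc = marker.ncol();
  NumericMatrix J(nr, nc);
  for (int i = 0; i < nr * nc; ++i)
    J[i] = std::min(marker[i], mask[i]);
  // raster scan
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double m = J(r, c);
      if (r > 0) m = std::max(m, J(r - 1, c));
      if (c > 0) m = std::max(m, J(r, c - 1));
      if (r > 0 && c > 0) m = std::max(m, J(r - 1, c - 1));
      if (r < nr - 1 && c > 0) m = std::max(m, J(r + 1, c - 1));
      J(r, c) = std::min(m, mask(r, c));
    }
  // anti-raster scan, queueing pixels that can still propagate
  std::queue<int> fifo;
  for (int c = nc - 1; c >= 0; --c)
    for (int r = nr - 1; r >= 0; --r) {
      double m = J(r, c);
      if (r < nr - 1) m = std::max(m, J(r + 1, c));
      if (c < nc - 1) m = std::max(m, J(r, c + 1));
      if (r < nr - 1 && c < nc - 1) m = std::max(m, J(r + 1, c + 1));
      if (r > 0 && c < nc - 1) m = std::max(m, J(r - 1, c + 1));
      J(r, c) = std::min(m, mask(r, c));
      for (int k = 0; k < 8; ++k) {
        int r2 = r + DR8[k], c2 = c + DC8[k];
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
        if (J(r2, c2) < J(r, c) && J(r2, c2) < mask(r2, c2)) {
          fifo.push(r + c * nr);
          break;
        }
      }
    }
  while (!fifo.empty()) {
    int idx = fifo.front(); fifo.pop();
    int r = idx % nr, c = idx / nr;
    for (int k = 0; k < 8; ++k) {
      int r2 = r + DR8[k], c2 = c + DC8[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (J(r2, c2) < J(r, c) && mask(r2, c2) != J(r2, c2)) {
        J(r2, c2) = std::min(J(r, c), mask(r2, c2));
        fifo.push(r2 + c2 * nr);
      }
    }
  }
  return J;
}

// Regional maxima of f restricted to a support mask: plateaus with no
// strictly greater 8-neighbour inside the support.
// [[Rcpp::export]]
LogicalMatrix cpp_regional_maxima(const NumericMatrix& f,
                                  const LogicalMatrix& support) {
  const int nr = f.nrow(), nc = f.ncol();
  LogicalMatrix out(nr, nc);
  IntegerMatrix seen(nr, nc);
  std::vector<int> plateau;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (!support(r, c) || seen(r, c)) continue;
      double v = f(r, c);
      bool is_max = true;
      plateau.clear();
      stack.clear();
      stack.push_back(r + c * nr);
      seen(r, c) = 1;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        plateau.push_back(idx);
        int rr = idx % nr, cc = idx / nr;
        for (int k = 0; k < 8; ++k) {
          int r2 = rr + DR8[k], c2 = cc + DC8[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (!support(r2, c2)) continue;
          double v2 = f(r2, c2);
          if (v2 > v) is_max = false;
          else if (v2 == v && !seen(r2, c2)) {
            seen(r2, c2) = 1;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
      if (is_max)
        for (size_t i = 0; i < plateau.size(); ++i)
          out[plateau[i]] = true;
    }
  return out;
}

// Marker-controlled watershed: flood `elevation` (ascending) from labelled
// markers inside `support`; every support pixel ends up with a marker label.
// [[Rcpp::export]]
IntegerMatrix cpp_watershed(const NumericMatrix& elevation,
                            const IntegerMatrix& markers,
                            const LogicalMatrix& support) {
  const int nr = elevation.nrow(), nc = elevation.ncol();
  IntegerMatrix lab(nr, nc);
  struct Node {
    double elev;
    long order;
    int idx;
  };
  struct Cmp {
    bool operator()(const Node& a, const Node& b) const {
      if (a.elev != b.elev) return a.elev > b.elev;
      return a.order > b.order;  // FIFO among equal elevations
    }
  };
  std::priority_queue<Node, std::vector<Node>, Cmp> pq;
  long order = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (support(r, c) && markers(r, c) > 0) {
        lab(r, c) = markers(r, c);
        pq.push({elevation(r, c), order++, r + c * nr});
      }
  while (!pq.empty()) {
    Node nd = pq.top(); pq.pop();
    int r = nd.idx % nr, c = nd.idx / nr;
    int l = lab(r, c);
    for (int k = 0; k < 8; ++k) {
      int r2 = r + DR8[k], c2 = c + DC8[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (!support(r2, c2) || lab(r2, c2) != 0) continue;
      lab(r2, c2) = l;
      pq.push({elevation(r2, c2), order++, r2 + c2 * nr});
    }
  }
  return lab;
}

// Separable Gaussian blur with edge replication.
// [[Rcpp::export]]
NumericMatrix cpp_gaussian_blur(const NumericMatrix& img, double sigma) {
  const int nr = img.nrow(), nc = img.ncol();
  if (sigma <= 0) return clone(img);
  int half = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * half + 1);
  double s = 0;
  for (int i = -half; i <= half; ++i) {
    k[i + half] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + half];
  }
  for (size_t i = 0; i < k.size(); ++i) k[i] /= s;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double acc = 0;
      for (int i = -half; i <= half; ++i) {
        int r2 = std::min(std::max(r + i, 0), nr - 1);
        acc += k[i + half] * img(r2, c);
      }
      tmp(r, c) = acc;
    }
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double acc = 0;
      for (int i = -half; i <= half; ++i) {
        int c2 = std::min(std::max(c + i, 0), nc - 1);
        acc += k[i + half] * tmp(r, c2);
      }
      out(r, c) = acc;
    }
  return out;
}
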