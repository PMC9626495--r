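#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Pixel index helpers: images are R matrices (column-major), edge handling is
// replication (clamp), matching the behaviour documented for the filters.
static inline int clampi(int x, int lo, int hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

static inline void sort2(double& a, double& b) {
  if (b < a) std::swap(a, b);
}

// Median of 9 by a 19-exchange sorting network (Paeth).
static inline double med9(double p0, double p1, double p2, double p3,
                          double p4, double p5, double p6, double p7,
                          double p8) {
  sort2(p1, p2); sort2(p4, p5); sort2(p7, p8);
  sort2(p0, p1); sort2(p3, p4); sort2(p6, p7);
  sort2(p1, p2); sort2(p4, p5); sort2(p7, p8);
  sort2(p0, p3); sort2(p5, p8); sort2(p4, p7);
  sort2(p3, p6); sort2(p1, p4); sort2(p2, p5);
  sort2(p4, p7); sort2(p4, p2); sort2(p6, p4);
  sort2(p4, p2);
  return p4;
}

// [[Rcpp::export]]
NumericMatrix cpp_median3x3(NumericMatrix img) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  const double* x = img.begin();
  double* o = out.begin();
  if (nr >= 3 && nc >= 3) {
    // interior: direct column-major offsets, no boundary clamping
    for (int j = 1; j < nc - 1; ++j) {
      const double* c0 = x + (size_t)(j - 1) * nr;
      const double* c1 = x + (size_t)j * nr;
      const double* c2 = x + (size_t)(j + 1) * nr;
      double* po = o + (size_t)j * nr;
      for (int i = 1; i < nr - 1; ++i) {
        po[i] = med9(c0[i - 1], c0[i], c0[i + 1],
                     c1[i - 1], c1[i], c1[i + 1],
                     c2[i - 1], c2[i], c2[i + 1]);
      }
    }
  }
  // borders: edge replication
  double win[9];
  for (int j = 0; j < nc; ++j) {
    const bool border_col = (j == 0 || j == nc - 1);
    for (int i = 0; i < nr; ++i) {
      if (!border_col && i != 0 && i != nr - 1) {
        if (nr >= 3 && nc >= 3) continue;
      }
      int k = 0;
      for (int dj = -1; dj <= 1; ++dj) {
        int jj = clampi(j + dj, 0, nc - 1);
        for (int di = -1; di <= 1; ++di) {
          int ii = clampi(i + di, 0, nr - 1);
          win[k++] = x[(size_t)jj * nr + ii];
        }
      }
      std::nth_element(win, win + 4, win + 9);
      o[(size_t)j * nr + i] = win[4];
    }
  }
  return out;
}

// Grayscale erosion over an explicit footprint given as (dr, dc) offset pairs.
// The 5-pixel cross (the radius-0.5 kernel) gets a dedicated fast path.
// [[Rcpp::export]]
NumericMatrix cpp_min_filter(NumericMatrix img, IntegerMatrix offsets) {
  const int nr = img.nrow(), nc = img.ncol(), no = offsets.nrow();
  NumericMatrix out(nr, nc);
  if (no == 5 && nr >= 3 && nc >= 3) {
    bool is_cross = true;
    for (int o = 0; o < no; ++o) {
      int a = std::abs(offsets(o, 0)) + std::abs(offsets(o, 1));
      if (a > 1) { is_cross = false; break; }
    }
    if (is_cross) {
      const double* x = img.begin();
      double* od = out.begin();
      for (int j = 1; j < nc - 1; ++j) {
        const double* c0 = x + (size_t)(j - 1) * nr;
        const double* c1 = x + (size_t)j * nr;
        const double* c2 = x + (size_t)(j + 1) * nr;
        double* po = od + (size_t)j * nr;
        for (int i = 1; i < nr - 1; ++i) {
          double m = c1[i];
          if (c1[i - 1] < m) m = c1[i - 1];
          if (c1[i + 1] < m) m = c1[i + 1];
          if (c0[i] < m) m = c0[i];
          if (c2[i] < m) m = c2[i];
          po[i] = m;
        }
      }
      for (int j = 0; j < nc; ++j) {
        const bool border_col = (j == 0 || j == nc - 1);
        for (int i = 0; i < nr; ++i) {
          if (!border_col && i != 0 && i != nr - 1) continue;
          double m = R_PosInf;
          for (int o = 0; o < no; ++o) {
            int ii = clampi(i + offsets(o, 0), 0, nr - 1);
            int jj = clampi(j + offsets(o, 1), 0, nc - 1);
            double v = x[(size_t)jj * nr + ii];
            if (v < m) m = v;
          }
          od[(size_t)j * nr + i] = m;
        }
      }
      return out;
    }
  }
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double m = R_PosInf;
      for (int o = 0; o < no; ++o) {
        int ii = clampi(i + offsets(o, 0), 0, nr - 1);
        int jj = clampi(j + offsets(o, 1), 0, nc - 1);
        double v = img(ii, jj);
        if (v < m) m = v;
      }
      out(i, j) = m;
    }
  }
  return out;
}

// 1-D lower-envelope transform d(p) = min_q f(q) + a (p-q)^2, computed in
// O(n) by the lower-envelope-of-parabolas construction. With `lower = false`
// the upper envelope (morphological dilation by the paraboloid) is returned.
static void parab_1d(const double* f, double* d, int n, double a, bool lower,
                     std::vector<int>& v, std::vector<double>& z,
                     std::vector<double>& fb) {
  for (int i = 0; i < n; ++i) fb[i] = lower ? f[i] : -f[i];
  // Intersection of the parabolas rooted at q and p: where the one at q
  // takes over the lower envelope.
  auto intersect = [&](int q, int p) {
    return ((fb[q] + a * (double)q * q) - (fb[p] + a * (double)p * p)) /
           (2.0 * a * (double)(q - p));
  };
  int k = 0;
  v[0] = 0;
  z[0] = R_NegInf;
  z[1] = R_PosInf;
  for (int q = 1; q < n; ++q) {
    double s = intersect(q, v[k]);
    while (k > 0 && s <= z[k]) {
      --k;
      s = intersect(q, v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = R_PosInf;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)q - v[k];
    double val = fb[v[k]] + a * dq * dq;
    d[q] = lower ? val : -val;
  }
}

static void parab_pass(NumericMatrix& m, double a, bool lower, bool by_row) {
  const int nr = m.nrow(), nc = m.ncol();
  const int n = by_row ? nc : nr;
  std::vector<int> v(n);
  std::vector<double> z(n + 1), fb(n), f(n), d(n);
  if (by_row) {
    for (int i = 0; i < nr; ++i) {
      for (int j = 0; j < nc; ++j) f[j] = m(i, j);
      parab_1d(f.data(), d.data(), n, a, lower, v, z, fb);
      for (int j = 0; j < nc; ++j) m(i, j) = d[j];
    }
  } else {
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) f[i] = m(i, j);
      parab_1d(f.data(), d.data(), n, a, lower, v, z, fb);
      for (int i = 0; i < nr; ++i) m(i, j) = d[i];
    }
  }
}

// Rolling-ball background estimate, paraboloid variant: grey opening with the
// elliptic paraboloid z = (x^2 + y^2) / (2 r) that osculates a ball of radius
// r at its bottom. Separable: the quadratic structuring function splits into
// independent row and column passes.
// [[Rcpp::export]]
NumericMatrix cpp_rolling_background(NumericMatrix img, double radius) {
  if (radius <= 0) stop("rolling radius must be > 0");
  const double a = 1.0 / (2.0 * radius);
  NumericMatrix bg = clone(img);
  parab_pass(bg, a, true, false);   // erode columns
  parab_pass(bg, a, true, true);    // erode rows
  parab_pass(bg, a, false, false);  // dilate columns
  parab_pass(bg, a, false, true);   // dilate rows
  return bg;
}

// Connected-component labelling of a binary mask (4- or 8-connectivity),
// labels assigned 1..k in raster (column-major) order of first encounter.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nnb = (connectivity == 8) ? 8 : 4;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.push_back(i + j * nr);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int ci = idx % nr, cj = idx / nr;
        for (int o = 0; o < nnb; ++o) {
          int ii = ci + dr8[o], jj = cj + dc8[o];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (mask(ii, jj) && lab(ii, jj) == 0) {
            lab(ii, jj) = next;
            stack.push_back(ii + jj * nr);
          }
        }
      }
    }
  }
  return lab;
}
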