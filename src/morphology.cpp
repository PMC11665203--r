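// Low-level image primitives: separable convolution, exact Euclidean
// distance transform, Zhang-Suen thinning, connected-component labeling.
// All routines treat matrices in R's column-major layout (row i, col j).
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
#include <limits>

using namespace Rcpp;

// symmetric (half-sample) boundary reflection
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// [[Rcpp::export]]
NumericMatrix cpp_sepconv(NumericMatrix img, NumericVector krow, NumericVector kcol) {
  const int nr = img.nrow(), nc = img.ncol();
  const int hr = (krow.size() - 1) / 2, hc = (kcol.size() - 1) / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  // convolve along rows (vertical direction, index i) with krow
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int t = -hr; t <= hr; ++t)
        acc += krow[t + hr] * img(reflect_idx(i + t, nr), j);
      tmp(i, j) = acc;
    }
  }
  // convolve along columns (horizontal direction, index j) with kcol
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int t = -hc; t <= hc; ++t)
        acc += kcol[t + hc] * tmp(i, reflect_idx(j + t, nc));
      out(i, j) = acc;
    }
  }
  return out;
}

// 1-D squared distance transform (Felzenszwalb & Huttenlocher)
static void dt1d(const std::vector<double> &f, std::vector<double> &d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
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

// Exact Euclidean distance (in pixels) from each TRUE pixel to the nearest
// FALSE pixel.  FALSE pixels get 0.  Pixels of an all-TRUE image get Inf.
// [[Rcpp::export]]
NumericMatrix cpp_edt(LogicalMatrix m) {
  const int nr = m.nrow(), nc = m.ncol();
  const double INF = 1e20;
  NumericMatrix g(nr, nc);
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  // columns first
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) f[i] = m(i, j) ? INF : 0.0;
    dt1d(f, d, nr);
    for (int i = 0; i < nr; ++i) g(i, j) = d[i];
  }
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) f[j] = g(i, j);
    dt1d(f, d, nc);
    for (int j = 0; j < nc; ++j) g(i, j) = d[j];
  }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      g(i, j) = (g(i, j) >= INF) ? R_PosInf : std::sqrt(g(i, j));
  return g;
}

// Zhang-Suen thinning: iterative two-subfield deletion until stable.
// Produces an 8-connected, topology-preserving skeleton that is a subset
// of the input mask.
// [[Rcpp::export]]
LogicalMatrix cpp_thin(LogicalMatrix m) {
  const int nr = m.nrow(), nc = m.ncol();
  std::vector<unsigned char> img(nr * nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      img[i + j * nr] = m(i, j) ? 1 : 0;

  auto at = [&](int i, int j) -> unsigned char {
    if (i < 0 || i >= nr || j < 0 || j >= nc) return 0;
    return img[i + j * nr];
  };

  bool changed = true;
  std::vector<int> kill;
  while (changed) {
    changed = false;
    for (int sub = 0; sub < 2; ++sub) {
      kill.clear();
      for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
          if (!img[i + j * nr]) continue;
          // neighbours p2..p9 clockwise starting north
          unsigned char p2 = at(i - 1, j),     p3 = at(i - 1, j + 1);
          unsigned char p4 = at(i, j + 1),     p5 = at(i + 1, j + 1);
          unsigned char p6 = at(i + 1, j),     p7 = at(i + 1, j - 1);
          unsigned char p8 = at(i, j - 1),     p9 = at(i - 1, j - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (sub == 0) {
            if ((p2 * p4 * p6) != 0 || (p4 * p6 * p8) != 0) continue;
          } else {
            if ((p2 * p4 * p8) != 0 || (p2 * p6 * p8) != 0) continue;
          }
          kill.push_back(i + j * nr);
        }
      }
      if (!kill.empty()) {
        changed = true;
        for (size_t t = 0; t < kill.size(); ++t) img[kill[t]] = 0;
      }
    }
  }
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = img[i + j * nr] != 0;
  return out;
}

// Connected-component labeling (BFS), connectivity 4 or 8.
// [[Rcpp::export]]
IntegerMatrix cpp_label(LogicalMatrix m, int connectivity = 8) {
  const int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  const int di8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dj8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int di4[4] = {-1, 0, 0, 1};
  const int dj4[4] = {0, -1, 1, 0};
  const int *di = (connectivity == 4) ? di4 : di8;
  const int *dj = (connectivity == 4) ? dj4 : dj8;
  const int nn = (connectivity == 4) ? 4 : 8;
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int j0 = 0; j0 < nc; ++j0) {
    for (int i0 = 0; i0 < nr; ++i0) {
      if (!m(i0, j0) || lab(i0, j0) != 0) continue;
      lab(i0, j0) = ++next;
      q.push(std::make_pair(i0, j0));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        for (int t = 0; t < nn; ++t) {
          int ii = p.first + di[t], jj = p.second + dj[t];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (m(ii, jj) && lab(ii, jj) == 0) {
            lab(ii, jj) = next;
            q.push(std::make_pair(ii, jj));
          }
        }
      }
    }
  }
  return lab;
}
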