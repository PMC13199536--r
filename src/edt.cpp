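#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// 1D lower-envelope pass applied separably along the three axes.
// f: squared distances (INF where no feature yet), in-place per line.
static void edt_1d(std::vector<double>& f, std::vector<double>& d,
                   std::vector<int>& v, std::vector<double>& z,
                   int n, double step2) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[0]] == INF) { // first finite parabola
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF; continue;
    }
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + step2 * q * q) - (f[p] + step2 * p * p)) / (2.0 * step2 * (q - p));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  if (f[v[0]] == INF) { // whole line empty
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    int p = v[k];
    d[q] = step2 * (q - p) * (q - p) + f[p];
  }
}

// [[Rcpp::export]]
NumericVector edt3d_cpp(LogicalVector feature, IntegerVector dims,
                        NumericVector spacing) {
  const double INF = std::numeric_limits<double>::infinity();
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = feature[i] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  double s2 = spacing[0] * spacing[0];
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      for (int i = 0; i < nx; ++i) f[i] = out[base + i];
      edt_1d(f, d, v, z, nx, s2);
      for (int i = 0; i < nx; ++i) out[base + i] = d[i];
    }
  // pass along y
  s2 = spacing[1] * spacing[1];
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + i;
      for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)j * nx];
      edt_1d(f, d, v, z, ny, s2);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)j * nx] = d[j];
    }
  // pass along z
  s2 = spacing[2] * spacing[2];
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)j * nx + i;
      for (int k = 0; k < nz; ++k) f[k] = out[base + (R_xlen_t)k * nxy];
      edt_1d(f, d, v, z, nz, s2);
      for (int k = 0; k < nz; ++k) out[base + (R_xlen_t)k * nxy] = d[k];
    }
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (out[i] == INF) ? R_PosInf : std::sqrt(out[i]);
  return out;
}

// Largest 6-connected component of a 3D logical mask.
// [[Rcpp::export]]
LogicalVector largest_component_cpp(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<int> label(n, 0);
  std::vector<R_xlen_t> stack;
  int ncomp = 0;
  R_xlen_t best_size = 0;
  int best_label = 0;
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || label[s]) continue;
    ++ncomp;
    R_xlen_t size = 0;
    stack.clear();
    stack.push_back(s);
    label[s] = ncomp;
    while (!stack.empty()) {
      R_xlen_t p = stack.back();
      stack.pop_back();
      ++size;
      int k = p / nxy;
      int j = (p - (R_xlen_t)k * nxy) / nx;
      int i = p - (R_xlen_t)k * nxy - (R_xlen_t)j * nx;
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int q = 0; q < 6; ++q) {
        int ii = i + di[q], jj = j + dj[q], kk = k + dk[q];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
        R_xlen_t pp = (R_xlen_t)kk * nxy + (R_xlen_t)jj * nx + ii;
        if (mask[pp] && !label[pp]) { label[pp] = ncomp; stack.push_back(pp); }
      }
    }
    if (size > best_size) { best_size = size; best_label = ncomp; }
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = (label[i] == best_label && best_label > 0);
  return out;
}
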