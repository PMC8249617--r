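#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Felzenszwalb & Huttenlocher 1D squared distance transform with a grid
// step w: d[i] = min_j f[j] + w^2 (i-j)^2
static void dt1d(std::vector<double>& f, double w, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& zb) {
  int n = f.size();
  double w2 = w * w;
  int k = 0;
  v[0] = 0;
  zb[0] = -std::numeric_limits<double>::infinity();
  zb[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
      if (s <= zb[k]) --k; else break;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double dq = (double)(q - v[k]);
    d[q] = w2 * dq * dq + f[v[k]];
  }
}

// anisotropic Euclidean distance (um) of each foreground voxel to the
// nearest background voxel; background voxels get 0
// [[Rcpp::export]]
NumericVector cpp_edt(IntegerVector mask, IntegerVector dims, NumericVector spacing) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  size_t st = (size_t)nz * ny, n = (size_t)nz * ny * nx;
  const double INF = 1e30;
  std::vector<double> a(n);
  for (size_t i = 0; i < n; ++i) a[i] = mask[i] ? INF : 0.0;
  int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), d(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);
  // z axis
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      size_t base = (size_t)nz * y + st * x;
      for (int z = 0; z < nz; ++z) f[z] = a[base + z];
      f.resize(nz); dt1d(f, spacing[0], d, v, zb); f.resize(nmax);
      for (int z = 0; z < nz; ++z) a[base + z] = d[z];
    }
  // y axis
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      size_t base = (size_t)z + st * x;
      for (int y = 0; y < ny; ++y) f[y] = a[base + (size_t)nz * y];
      f.resize(ny); dt1d(f, spacing[1], d, v, zb); f.resize(nmax);
      for (int y = 0; y < ny; ++y) a[base + (size_t)nz * y] = d[y];
    }
  // x axis
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      size_t base = (size_t)z + (size_t)nz * y;
      for (int x = 0; x < nx; ++x) f[x] = a[base + st * x];
      f.resize(nx); dt1d(f, spacing[2], d, v, zb); f.resize(nmax);
      for (int x = 0; x < nx; ++x) a[base + st * x] = d[x];
    }
  NumericVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = std::sqrt(a[i]);
  return out;
}
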