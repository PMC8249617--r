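#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Volumes are passed as flat numeric vectors with dims (nz, ny, nx) and
// linear index z + nz*(y + ny*x) (R column-major on an array indexed
// [z, y, x]). 2D images are handled as single-slice volumes by the R layer.

static inline int reflect(int i, int n) {
  // symmetric boundary: ... 2 1 0 | 0 1 2 ... n-1 | n-1 n-2 ...
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

static std::vector<double> gauss_kernel(double sigma) {
  int r = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double& v : k) v /= s;
  return k;
}

// separable convolution along one axis (0=z, 1=y, 2=x)
static void conv_axis(std::vector<double>& a, int nz, int ny, int nx,
                      int axis, const std::vector<double>& k) {
  int r = ((int)k.size() - 1) / 2;
  int n = axis == 0 ? nz : (axis == 1 ? ny : nx);
  std::vector<double> line(n);
  if (axis == 0) {
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        size_t base = (size_t)nz * (y + (size_t)ny * x);
        for (int z = 0; z < n; ++z) {
          double s = 0.0;
          for (int j = -r; j <= r; ++j) s += k[j + r] * a[base + reflect(z + j, n)];
          line[z] = s;
        }
        for (int z = 0; z < n; ++z) a[base + z] = line[z];
      }
  } else if (axis == 1) {
    for (int x = 0; x < nx; ++x)
      for (int z = 0; z < nz; ++z) {
        size_t base = (size_t)z + (size_t)nz * ny * x;
        for (int y = 0; y < n; ++y) {
          double s = 0.0;
          for (int j = -r; j <= r; ++j)
            s += k[j + r] * a[base + (size_t)nz * reflect(y + j, n)];
          line[y] = s;
        }
        for (int y = 0; y < n; ++y) a[base + (size_t)nz * y] = line[y];
      }
  } else {
    size_t st = (size_t)nz * ny;
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        size_t base = (size_t)z + (size_t)nz * y;
        for (int x = 0; x < n; ++x) {
          double s = 0.0;
          for (int j = -r; j <= r; ++j) s += k[j + r] * a[base + st * reflect(x + j, n)];
          line[x] = s;
        }
        for (int x = 0; x < n; ++x) a[base + st * x] = line[x];
      }
  }
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_filter(NumericVector img, IntegerVector dims,
                                  NumericVector sigma) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  std::vector<double> a(img.begin(), img.end());
  for (int ax = 0; ax < 3; ++ax) {
    if (sigma[ax] > 0) conv_axis(a, nz, ny, nx, ax, gauss_kernel(sigma[ax]));
  }
  NumericVector out(a.begin(), a.end());
  return out;
}

// n iterations of binary dilation with a 3x3 (8-connected) element applied
// independently to every XY slice
// [[Rcpp::export]]
IntegerVector cpp_dilate2d(IntegerVector mask, IntegerVector dims, int iter) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  std::vector<int> a(mask.begin(), mask.end()), b(a.size());
  size_t st = (size_t)nz * ny;
  for (int it = 0; it < iter; ++it) {
    for (int z = 0; z < nz; ++z)
      for (int x = 0; x < nx; ++x)
        for (int y = 0; y < ny; ++y) {
          int v = 0;
          for (int dx = -1; dx <= 1 && !v; ++dx)
            for (int dy = -1; dy <= 1 && !v; ++dy) {
              int yy = y + dy, xx = x + dx;
              if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
              if (a[(size_t)z + (size_t)nz * yy + st * xx]) v = 1;
            }
          b[(size_t)z + (size_t)nz * y + st * x] = v;
        }
    a.swap(b);
  }
  return IntegerVector(a.begin(), a.end());
}

// 3D median filter over a spherical neighbourhood of radius r voxels;
// border voxels use the in-bounds part of the neighbourhood
// [[Rcpp::export]]
NumericVector cpp_median3d(NumericVector img, IntegerVector dims, int r) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  std::vector<std::array<int, 3>> off;
  for (int dz = -r; dz <= r; ++dz)
    for (int dy = -r; dy <= r; ++dy)
      for (int dx = -r; dx <= r; ++dx)
        if (dz * dz + dy * dy + dx * dx <= r * r) off.push_back({dz, dy, dx});
  NumericVector out(img.size());
  std::vector<double> buf;
  buf.reserve(off.size());
  size_t st = (size_t)nz * ny;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        buf.clear();
        for (const auto& o : off) {
          int zz = z + o[0], yy = y + o[1], xx = x + o[2];
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
          buf.push_back(img[(size_t)zz + (size_t)nz * yy + st * xx]);
        }
        size_t m = buf.size() / 2;
        std::nth_element(buf.begin(), buf.begin() + m, buf.end());
        out[(size_t)z + (size_t)nz * y + st * x] = buf[m];
      }
  return out;
}

// trilinear resampling from spacing_in to spacing_out; both grids share the
// origin and the convention physical = index * spacing
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector img, IntegerVector dims,
                           NumericVector sp_in, IntegerVector dims_out,
                           NumericVector sp_out) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  int oz = dims_out[0], oy = dims_out[1], ox = dims_out[2];
  size_t st = (size_t)nz * ny;
  NumericVector out((size_t)oz * oy * ox);
  for (int x = 0; x < ox; ++x)
    for (int y = 0; y < oy; ++y)
      for (int z = 0; z < oz; ++z) {
        double tz = z * sp_out[0] / sp_in[0];
        double ty = y * sp_out[1] / sp_in[1];
        double tx = x * sp_out[2] / sp_in[2];
        int z0 = std::min(std::max((int)std::floor(tz), 0), nz - 1);
        int y0 = std::min(std::max((int)std::floor(ty), 0), ny - 1);
        int x0 = std::min(std::max((int)std::floor(tx), 0), nx - 1);
        int z1 = std::min(z0 + 1, nz - 1), y1 = std::min(y0 + 1, ny - 1),
            x1 = std::min(x0 + 1, nx - 1);
        double fz = std::min(std::max(tz - z0, 0.0), 1.0);
        double fy = std::min(std::max(ty - y0, 0.0), 1.0);
        double fx = std::min(std::max(tx - x0, 0.0), 1.0);
        double v = 0.0;
        for (int a = 0; a <= 1; ++a)
          for (int b = 0; b <= 1; ++b)
            for (int c = 0; c <= 1; ++c) {
              double w = (a ? fz : 1 - fz) * (b ? fy : 1 - fy) * (c ? fx : 1 - fx);
              v += w * img[(size_t)(a ? z1 : z0) + (size_t)nz * (b ? y1 : y0) +
                           st * (c ? x1 : x0)];
            }
        out[(size_t)z + (size_t)oz * y + (size_t)oz * oy * x] = v;
      }
  return out;
}

// minimum distance from every voxel centre to a polyline (physical units),
// evaluated only within `rmax` of the polyline's bounding box; elsewhere Inf.
// pts is m x 3 (z,y,x) in um. Used by the phantom renderer.
// [[Rcpp::export]]
NumericVector cpp_polyline_distance(NumericVector pts, IntegerVector dims,
                                    NumericVector spacing, double rmax) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  int m = pts.size() / 3;
  size_t st = (size_t)nz * ny;
  NumericVector out((size_t)nz * ny * nx, R_PosInf);
  for (int s = 0; s + 1 < m; ++s) {
    double az = pts[s], ay = pts[s + m], ax = pts[s + 2 * m];
    double bz = pts[s + 1], by = pts[s + 1 + m], bx = pts[s + 1 + 2 * m];
    double lz = std::min(az, bz) - rmax, hz = std::max(az, bz) + rmax;
    double ly = std::min(ay, by) - rmax, hy = std::max(ay, by) + rmax;
    double lx = std::min(ax, bx) - rmax, hx = std::max(ax, bx) + rmax;
    int z0 = std::max(0, (int)std::ceil(lz / spacing[0]));
    int z1 = std::min(nz - 1, (int)std::floor(hz / spacing[0]));
    int y0 = std::max(0, (int)std::ceil(ly / spacing[1]));
    int y1 = std::min(ny - 1, (int)std::floor(hy / spacing[1]));
    int x0 = std::max(0, (int)std::ceil(lx / spacing[2]));
    int x1 = std::min(nx - 1, (int)std::floor(hx / spacing[2]));
    double dz = bz - az, dy = by - ay, dx = bx - ax;
    double len2 = dz * dz + dy * dy + dx * dx;
    for (int x = x0; x <= x1; ++x)
      for (int y = y0; y <= y1; ++y)
        for (int z = z0; z <= z1; ++z) {
          double pz = z * spacing[0], py = y * spacing[1], px = x * spacing[2];
          double t = 0.0;
          if (len2 > 0)
            t = ((pz - az) * dz + (py - ay) * dy + (px - ax) * dx) / len2;
          t = std::min(std::max(t, 0.0), 1.0);
          double qz = az + t * dz - pz, qy = ay + t * dy - py, qx = ax + t * dx - px;
          double d = std::sqrt(qz * qz + qy * qy + qx * qx);
          size_t i = (size_t)z + (size_t)nz * y + st * x;
          if (d < out[i]) out[i] = d;
        }
  }
  return out;
}
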