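#include <Rcpp.h>
#include <vector>
#include <array>
#include <queue>
using namespace Rcpp;

// index convention: z + nz*(y + ny*x)

static std::vector<std::array<int, 3>> conn_offsets(int conn) {
  std::vector<std::array<int, 3>> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int n = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (n == 0) continue;
        if (conn == 6 && n > 1) continue;
        if (conn == 18 && n > 2) continue;
        off.push_back({dz, dy, dx});
      }
  return off;
}

// 3D connected-component labelling, connectivity in {6,18,26}
// [[Rcpp::export]]
IntegerVector cpp_label3d(IntegerVector mask, IntegerVector dims, int conn) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  size_t st = (size_t)nz * ny, n = (size_t)nz * ny * nx;
  auto off = conn_offsets(conn);
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<size_t> stack;
  for (size_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    lab[i] = ++next;
    stack.push_back(i);
    while (!stack.empty()) {
      size_t cur = stack.back();
      stack.pop_back();
      int x = cur / st, rem = cur % st, y = rem / nz, z = rem % nz;
      for (const auto& o : off) {
        int zz = z + o[0], yy = y + o[1], xx = x + o[2];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        size_t j = (size_t)zz + (size_t)nz * yy + st * xx;
        if (mask[j] && !lab[j]) {
          lab[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  return lab;
}

// per-label voxel count, centroid (voxel index sums), intensity sum, bbox
// [[Rcpp::export]]
List cpp_region_stats(IntegerVector lab, IntegerVector dims, NumericVector intens) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  size_t st = (size_t)nz * ny, n = (size_t)nz * ny * nx;
  int K = 0;
  for (size_t i = 0; i < n; ++i) K = std::max(K, lab[i]);
  NumericVector count(K), sz(K), sy(K), sx(K), si(K);
  IntegerVector z0(K, nz), z1(K, -1), y0(K, ny), y1(K, -1), x0(K, nx), x1(K, -1);
  for (size_t i = 0; i < n; ++i) {
    int l = lab[i];
    if (!l) continue;
    int x = i / st, rem = i % st, y = rem / nz, z = rem % nz;
    int k = l - 1;
    count[k] += 1;
    sz[k] += z; sy[k] += y; sx[k] += x;
    si[k] += intens[i];
    if (z < z0[k]) z0[k] = z; if (z > z1[k]) z1[k] = z;
    if (y < y0[k]) y0[k] = y; if (y > y1[k]) y1[k] = y;
    if (x < x0[k]) x0[k] = x; if (x > x1[k]) x1[k] = x;
  }
  return List::create(_["count"] = count, _["sz"] = sz, _["sy"] = sy,
                      _["sx"] = sx, _["sum_intensity"] = si,
                      _["z0"] = z0, _["z1"] = z1, _["y0"] = y0, _["y1"] = y1,
                      _["x0"] = x0, _["x1"] = x1);
}

// per-label surface area by summing exposed voxel faces (anisotropy aware)
// [[Rcpp::export]]
NumericVector cpp_region_surface(IntegerVector lab, IntegerVector dims,
                                 NumericVector spacing) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  size_t st = (size_t)nz * ny, n = (size_t)nz * ny * nx;
  int K = 0;
  for (size_t i = 0; i < n; ++i) K = std::max(K, lab[i]);
  NumericVector area(K);
  double az = spacing[1] * spacing[2];  // face normal to z
  double ay = spacing[0] * spacing[2];
  double ax = spacing[0] * spacing[1];
  const int dz[6] = {-1, 1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, -1, 1, 0, 0};
  const int dx[6] = {0, 0, 0, 0, -1, 1};
  const double fa[6] = {az, az, ay, ay, ax, ax};
  for (size_t i = 0; i < n; ++i) {
    int l = lab[i];
    if (!l) continue;
    int x = i / st, rem = i % st, y = rem / nz, z = rem % nz;
    for (int d = 0; d < 6; ++d) {
      int zz = z + dz[d], yy = y + dy[d], xx = x + dx[d];
      bool outside = zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx;
      if (outside || lab[(size_t)zz + (size_t)nz * yy + st * xx] != l)
        area[l - 1] += fa[d];
    }
  }
  return area;
}

// one sweep of lumen filling for one orientation: for every 2D slice,
// 4-connected background components that do not touch the slice border and
// whose physical area lies in [amin, amax] are set to foreground.
// orient: 0 = XY slices (fixed z), 1 = YZ slices (fixed x), 2 = XZ (fixed y)
// [[Rcpp::export]]
IntegerVector cpp_fill_lumens_once(IntegerVector mask, IntegerVector dims,
                                   int orient, double amin, double amax,
                                   double pixel_area) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  size_t st = (size_t)nz * ny;
  IntegerVector out = clone(mask);
  // slice geometry: (nu, nv) with an index function into the volume
  int ns, nu, nv;
  if (orient == 0) { ns = nz; nu = ny; nv = nx; }
  else if (orient == 1) { ns = nx; nu = nz; nv = ny; }
  else { ns = ny; nu = nz; nv = nx; }
  auto vidx = [&](int s, int u, int v) -> size_t {
    if (orient == 0) return (size_t)s + (size_t)nz * u + st * v;
    if (orient == 1) return (size_t)u + (size_t)nz * v + st * s;
    return (size_t)u + (size_t)nz * s + st * v;
  };
  std::vector<int> lab((size_t)nu * nv);
  std::vector<int> stack;
  for (int s = 0; s < ns; ++s) {
    std::fill(lab.begin(), lab.end(), 0);
    int next = 0;
    std::vector<int> count;
    std::vector<char> border;
    for (int u = 0; u < nu; ++u)
      for (int v = 0; v < nv; ++v) {
        if (out[vidx(s, u, v)] || lab[u + (size_t)nu * v]) continue;
        ++next;
        count.push_back(0);
        border.push_back(0);
        stack.clear();
        lab[u + (size_t)nu * v] = next;
        stack.push_back(u + nu * v);
        while (!stack.empty()) {
          int cur = stack.back();
          stack.pop_back();
          int cv = cur / nu, cu = cur % nu;
          count[next - 1]++;
          if (cu == 0 || cu == nu - 1 || cv == 0 || cv == nv - 1)
            border[next - 1] = 1;
          const int du[4] = {-1, 1, 0, 0}, dvv[4] = {0, 0, -1, 1};
          for (int d = 0; d < 4; ++d) {
            int uu = cu + du[d], vv = cv + dvv[d];
            if (uu < 0 || uu >= nu || vv < 0 || vv >= nv) continue;
            if (!out[vidx(s, uu, vv)] && !lab[uu + (size_t)nu * vv]) {
              lab[uu + (size_t)nu * vv] = next;
              stack.push_back(uu + nu * vv);
            }
          }
        }
      }
    for (int u = 0; u < nu; ++u)
      for (int v = 0; v < nv; ++v) {
        int l = lab[u + (size_t)nu * v];
        if (!l || border[l - 1]) continue;
        double a = count[l - 1] * pixel_area;
        if (a >= amin && a <= amax) out[vidx(s, u, v)] = 1;
      }
  }
  return out;
}
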