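#include <Rcpp.h>
#include <vector>
#include <queue>
#include <tuple>
#include <cmath>
using namespace Rcpp;

// Distance-ordered homotopic thinning to a curve skeleton.
// A voxel may be deleted when it is a simple point for (26-foreground,
// 6-background) connectivity — characterized by topological numbers
// T26(fg) == 1 and T6(bg) == 1 (Bertrand & Malandain) — and is not a curve
// endpoint (<= 1 foreground 26-neighbour). Voxels are visited in increasing
// order of their Euclidean distance to the background so that centrally
// located, maximally distant voxels survive.

static const int NB = 27;  // 3x3x3, center at 13

static inline int noff(int dz, int dy, int dx) {
  return (dz + 1) + 3 * (dy + 1) + 9 * (dx + 1);
}

// foreground 26-connected components in N26* must equal 1
static bool t26_is_one(const bool* nb) {
  int seen[NB] = {0};
  int comps = 0;
  for (int i = 0; i < NB; ++i) {
    if (i == 13 || !nb[i] || seen[i]) continue;
    ++comps;
    if (comps > 1) return false;
    int stack[NB], top = 0;
    stack[top++] = i;
    seen[i] = 1;
    while (top) {
      int c = stack[--top];
      int cx = c / 9, cy = (c % 9) / 3, cz = c % 3;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int zz = cz + dz, yy = cy + dy, xx = cx + dx;
            if (zz < 0 || zz > 2 || yy < 0 || yy > 2 || xx < 0 || xx > 2) continue;
            int j = zz + 3 * yy + 9 * xx;
            if (j == 13 || !nb[j] || seen[j]) continue;
            seen[j] = 1;
            stack[top++] = j;
          }
    }
  }
  return comps == 1;
}

// background 6-connected components within the 18-neighbourhood that are
// 6-adjacent to the centre must equal 1
static bool t6_is_one(const bool* nb) {
  // membership in the 18-neighbourhood: at most two non-zero offsets
  auto in18 = [](int i) {
    int dx = i / 9 - 1, dy = (i % 9) / 3 - 1, dz = i % 3 - 1;
    if (dz == 0 && dy == 0 && dx == 0) return false;
    return std::abs(dz) + std::abs(dy) + std::abs(dx) <= 2;
  };
  bool face[NB] = {false};
  face[noff(-1, 0, 0)] = face[noff(1, 0, 0)] = true;
  face[noff(0, -1, 0)] = face[noff(0, 1, 0)] = true;
  face[noff(0, 0, -1)] = face[noff(0, 0, 1)] = true;
  int seen[NB] = {0};
  int comps = 0;
  for (int i = 0; i < NB; ++i) {
    if (!face[i] || nb[i] || seen[i]) continue;  // seed only at face neighbours
    ++comps;
    if (comps > 1) return false;
    int stack[NB], top = 0;
    stack[top++] = i;
    seen[i] = 1;
    while (top) {
      int c = stack[--top];
      int cx = c / 9, cy = (c % 9) / 3, cz = c % 3;
      const int d6[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
      for (int d = 0; d < 6; ++d) {
        int zz = cz + d6[d][0], yy = cy + d6[d][1], xx = cx + d6[d][2];
        if (zz < 0 || zz > 2 || yy < 0 || yy > 2 || xx < 0 || xx > 2) continue;
        int j = zz + 3 * yy + 9 * xx;
        if (j == 13 || nb[j] || seen[j] || !in18(j)) continue;
        seen[j] = 1;
        stack[top++] = j;
      }
    }
  }
  return comps == 1;
}

// [[Rcpp::export]]
LogicalVector cpp_is_simple_point(LogicalVector neighborhood) {
  bool nb[NB];
  for (int i = 0; i < NB; ++i) nb[i] = neighborhood[i];
  return LogicalVector::create(t26_is_one(nb) && t6_is_one(nb));
}

// [[Rcpp::export]]
IntegerVector cpp_skeletonize(IntegerVector mask, IntegerVector dims,
                              NumericVector dist) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  size_t st = (size_t)nz * ny, n = (size_t)nz * ny * nx;
  std::vector<char> m(n);
  for (size_t i = 0; i < n; ++i) m[i] = mask[i] ? 1 : 0;

  auto gather = [&](int z, int y, int x, bool* nb) {
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          int zz = z + dz, yy = y + dy, xx = x + dx;
          bool v = false;
          if (zz >= 0 && zz < nz && yy >= 0 && yy < ny && xx >= 0 && xx < nx)
            v = m[(size_t)zz + (size_t)nz * yy + st * xx];
          nb[noff(dz, dy, dx)] = v;
        }
  };
  auto n26 = [&](const bool* nb) {
    int c = 0;
    for (int i = 0; i < NB; ++i)
      if (i != 13 && nb[i]) ++c;
    return c;
  };

  typedef std::tuple<double, long long, size_t> Item;  // (dist, seq, index)
  std::priority_queue<Item, std::vector<Item>, std::greater<Item>> pq;
  long long seq = 0;
  for (size_t i = 0; i < n; ++i)
    if (m[i]) pq.push(Item(dist[i], seq++, i));

  bool nb[NB];
  while (!pq.empty()) {
    size_t i = std::get<2>(pq.top());
    pq.pop();
    if (!m[i]) continue;
    int x = i / st, rem = i % st, y = rem / nz, z = rem % nz;
    gather(z, y, x, nb);
    int cnt = n26(nb);
    if (cnt <= 1) continue;  // endpoint or isolated: keep
    if (t26_is_one(nb) && t6_is_one(nb)) {
      m[i] = 0;
      // deleting a voxel may make neighbours deletable; requeue them
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int zz = z + dz, yy = y + dy, xx = x + dx;
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
              continue;
            size_t j = (size_t)zz + (size_t)nz * yy + st * xx;
            if (m[j]) pq.push(Item(dist[j], seq++, j));
          }
    }
  }
  IntegerVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = m[i];
  return out;
}
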