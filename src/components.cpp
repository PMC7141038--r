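#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Neighborhood offsets for a (row, col, plane) array stored column-major.
// connectivity: 2D (plane dim == 1): 4 or 8; 3D: 6, 18 or 26.
static std::vector<std::array<int, 3>> neighbor_offsets(int connectivity,
                                                        bool is3d) {
  std::vector<std::array<int, 3>> off;
  int zr = is3d ? 1 : 0;
  for (int dz = -zr; dz <= zr; ++dz) {
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        bool keep;
        if (!is3d) {
          keep = (connectivity == 8) || manh == 1;
        } else if (connectivity == 6) {
          keep = manh == 1;
        } else if (connectivity == 18) {
          keep = manh <= 2;
        } else {
          keep = true;  // 26
        }
        if (keep) off.push_back({dy, dx, dz});
      }
    }
  }
  return off;
}

// Label connected components of a logical mask (dims ny x nx x nz).
// Returns integer array of same dim: 0 background, components numbered from 1
// in decreasing order of voxel count (ties: first-encountered order).
// [[Rcpp::export(name = ".cc_label")]]
IntegerVector cc_label(LogicalVector mask, IntegerVector dim,
                       int connectivity) {
  int ny = dim[0], nx = dim[1], nz = dim.size() > 2 ? dim[2] : 1;
  bool is3d = nz > 1;
  R_xlen_t n = (R_xlen_t)ny * nx * nz;
  IntegerVector lab(n, 0);
  lab.attr("dim") = dim;
  std::vector<std::array<int, 3>> off = neighbor_offsets(connectivity, is3d);
  std::vector<R_xlen_t> stack;
  std::vector<R_xlen_t> sizes;  // per provisional label
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    R_xlen_t size = 0;
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      ++size;
      int y = (int)(v % ny);
      int x = (int)((v / ny) % nx);
      int z = (int)(v / ((R_xlen_t)ny * nx));
      for (auto &o : off) {
        int yy = y + o[0], xx = x + o[1], zz = z + o[2];
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
          continue;
        R_xlen_t w = (R_xlen_t)zz * ny * nx + (R_xlen_t)xx * ny + yy;
        if (mask[w] && lab[w] == 0) {
          lab[w] = next;
          stack.push_back(w);
        }
      }
    }
    sizes.push_back(size);
  }
  // Renumber so component 1 is the largest.
  std::vector<int> order(next);
  for (int i = 0; i < next; ++i) order[i] = i;
  std::stable_sort(order.begin(), order.end(),
                   [&](int a, int b) { return sizes[a] > sizes[b]; });
  std::vector<int> remap(next + 1, 0);
  for (int r = 0; r < next; ++r) remap[order[r] + 1] = r + 1;
  for (R_xlen_t s = 0; s < n; ++s)
    if (lab[s] != 0) lab[s] = remap[lab[s]];
  return lab;
}

// Flood fill from a seed linear index (0-based) over a mask; returns logical
// array marking the connected component containing the seed.
// [[Rcpp::export(name = ".cc_flood")]]
LogicalVector cc_flood(LogicalVector mask, IntegerVector dim, double seed0,
                       int connectivity) {
  int ny = dim[0], nx = dim[1], nz = dim.size() > 2 ? dim[2] : 1;
  bool is3d = nz > 1;
  R_xlen_t n = (R_xlen_t)ny * nx * nz;
  R_xlen_t seed = (R_xlen_t)seed0;
  LogicalVector out(n, false);
  out.attr("dim") = dim;
  if (seed < 0 || seed >= n || !mask[seed]) return out;
  std::vector<std::array<int, 3>> off = neighbor_offsets(connectivity, is3d);
  std::vector<R_xlen_t> stack;
  stack.push_back(seed);
  out[seed] = true;
  while (!stack.empty()) {
    R_xlen_t v = stack.back();
    stack.pop_back();
    int y = (int)(v % ny);
    int x = (int)((v / ny) % nx);
    int z = (int)(v / ((R_xlen_t)ny * nx));
    for (auto &o : off) {
      int yy = y + o[0], xx = x + o[1], zz = z + o[2];
      if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
        continue;
      R_xlen_t w = (R_xlen_t)zz * ny * nx + (R_xlen_t)xx * ny + yy;
      if (mask[w] && !out[w]) {
        out[w] = true;
        stack.push_back(w);
      }
    }
  }
  return out;
}

// 1D squared-distance transform (lower envelope of parabolas), sample
// spacing h. f holds squared distances; lines without background carry a
// large finite sentinel (chosen per image, small enough that adding h^2*q^2
// stays exact in double precision).
static void dt1d(const std::vector<double> &f, std::vector<double> &d,
                 double h) {
  const double INF = std::numeric_limits<double>::infinity();
  int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + h * h * q * q) - (f[v[k]] + h * h * v[k] * v[k])) /
               (2.0 * h * h * (q - v[k]));
    while (k > 0 && s <= z[k]) {
      --k;
      s = ((f[q] + h * h * q * q) - (f[v[k]] + h * h * v[k] * v[k])) /
          (2.0 * h * h * (q - v[k]));
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;  // intersections are stored in index units
    double dq = h * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// Euclidean distance transform of a logical mask with per-axis spacing
// (ny, nx, nz order): distance from each foreground voxel to the nearest
// background voxel, in physical units. Background voxels get 0. The image
// border is not treated as background.
// [[Rcpp::export(name = ".edt")]]
NumericVector edt(LogicalVector mask, IntegerVector dim,
                  NumericVector spacing) {
  int ny = dim[0], nx = dim[1], nz = dim.size() > 2 ? dim[2] : 1;
  R_xlen_t n = (R_xlen_t)ny * nx * nz;
  NumericVector out(n);
  out.attr("dim") = dim;
  // sentinel: strictly larger than any squared distance within the volume
  double sz = spacing.size() > 2 ? spacing[2] : 1.0;
  double big = 1.0 +
    (ny - 1.0) * (ny - 1.0) * spacing[0] * spacing[0] +
    (nx - 1.0) * (nx - 1.0) * spacing[1] * spacing[1] +
    (nz - 1.0) * (nz - 1.0) * sz * sz;
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] ? big : 0.0;

  std::vector<double> f, d;
  // pass along y (within columns)
  f.resize(ny); d.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)z * ny * nx + (R_xlen_t)x * ny;
      for (int y = 0; y < ny; ++y) f[y] = g[base + y];
      dt1d(f, d, spacing[0]);
      for (int y = 0; y < ny; ++y) g[base + y] = d[y];
    }
  // pass along x
  f.resize(nx); d.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)z * ny * nx + y;
      for (int x = 0; x < nx; ++x) f[x] = g[base + (R_xlen_t)x * ny];
      dt1d(f, d, spacing[1]);
      for (int x = 0; x < nx; ++x) g[base + (R_xlen_t)x * ny] = d[x];
    }
  // pass along z
  if (nz > 1) {
    f.resize(nz); d.resize(nz);
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        R_xlen_t base = (R_xlen_t)x * ny + y;
        for (int z = 0; z < nz; ++z) f[z] = g[base + (R_xlen_t)z * ny * nx];
        dt1d(f, d, spacing.size() > 2 ? spacing[2] : 1.0);
        for (int z = 0; z < nz; ++z) g[base + (R_xlen_t)z * ny * nx] = d[z];
      }
  }
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (g[i] >= big) ? R_PosInf : std::sqrt(g[i]);
  return out;
}
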