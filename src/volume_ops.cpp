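// 3D volume primitives for nucleus detection.
//
// Volumes are R arrays with dim = c(nx, ny, nz), x fastest (column-major),
// linear index = x + nx * (y + ny * z), 0-based here.
//
// EBImage's bwlabel/medianFilter/distmap act frame-wise in 2D, so the true
// volumetric versions needed for anisotropic z-stacks live here.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <limits>
#include <cmath>
using namespace Rcpp;

static inline int at(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// 26-connectivity connected-component labeling (BFS).
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int next_label = 0;
  std::vector<int> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next_label;
    lab[s] = next_label;
    stack.clear();
    stack.push_back((int)s);
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int z = cur / (nx * ny);
      int rem = cur - z * nx * ny;
      int y = rem / nx;
      int x = rem - y * nx;
      for (int dz = -1; dz <= 1; ++dz) {
        int zz = z + dz; if (zz < 0 || zz >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = y + dy; if (yy < 0 || yy >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int xx = x + dx; if (xx < 0 || xx >= nx) continue;
            int idx = at(xx, yy, zz, nx, ny);
            if (mask[idx] && !lab[idx]) { lab[idx] = next_label; stack.push_back(idx); }
          }
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// 3D median filter, cubic window of half-width `radius`, replicated borders.
// [[Rcpp::export]]
NumericVector cpp_medfilt3(NumericVector vol, IntegerVector dims, int radius) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  const int w = 2 * radius + 1;
  std::vector<double> win((size_t)w * w * w);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        size_t k = 0;
        for (int dz = -radius; dz <= radius; ++dz) {
          int zz = std::min(std::max(z + dz, 0), nz - 1);
          for (int dy = -radius; dy <= radius; ++dy) {
            int yy = std::min(std::max(y + dy, 0), ny - 1);
            for (int dx = -radius; dx <= radius; ++dx) {
              int xx = std::min(std::max(x + dx, 0), nx - 1);
              win[k++] = vol[at(xx, yy, zz, nx, ny)];
            }
          }
        }
        size_t mid = k / 2;
        std::nth_element(win.begin(), win.begin() + mid, win.begin() + k);
        out[at(x, y, z, nx, ny)] = win[mid];
      }
  out.attr("dim") = dims;
  return out;
}

// Separable cubic min (op = 0) / max (op = 1) filter, replicated borders.
static void axis_minmax(std::vector<double>& v, int nx, int ny, int nz,
                        int radius, int axis, bool take_max) {
  std::vector<double> line, res;
  int len = axis == 0 ? nx : (axis == 1 ? ny : nz);
  line.resize(len); res.resize(len);
  int n_outer1 = axis == 0 ? ny : nx;
  int n_outer2 = axis == 2 ? ny : nz;
  for (int a = 0; a < n_outer1; ++a)
    for (int b = 0; b < n_outer2; ++b) {
      for (int i = 0; i < len; ++i) {
        int x = axis == 0 ? i : a;
        int y = axis == 0 ? a : (axis == 1 ? i : b);
        int z = axis == 2 ? i : b;
        line[i] = v[at(x, y, z, nx, ny)];
      }
      for (int i = 0; i < len; ++i) {
        int lo = std::max(i - radius, 0), hi = std::min(i + radius, len - 1);
        double m = line[lo];
        for (int j = lo + 1; j <= hi; ++j)
          m = take_max ? std::max(m, line[j]) : std::min(m, line[j]);
        res[i] = m;
      }
      for (int i = 0; i < len; ++i) {
        int x = axis == 0 ? i : a;
        int y = axis == 0 ? a : (axis == 1 ? i : b);
        int z = axis == 2 ? i : b;
        v[at(x, y, z, nx, ny)] = res[i];
      }
    }
}

// [[Rcpp::export]]
NumericVector cpp_minmaxfilt3(NumericVector vol, IntegerVector dims, int radius,
                              bool take_max) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> v(vol.begin(), vol.end());
  for (int axis = 0; axis < 3; ++axis) axis_minmax(v, nx, ny, nz, radius, axis, take_max);
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = dims;
  return out;
}

// 1D squared-distance transform of a sampled function (Felzenszwalb &
// Huttenlocher), grid step h.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double h) {
  std::vector<int> v(n);
  std::vector<double> zi(n + 1);
  int k = 0;
  v[0] = 0;
  zi[0] = -std::numeric_limits<double>::infinity();
  zi[1] = std::numeric_limits<double>::infinity();
  const double h2 = h * h;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + h2 * q * q) - (f[p] + h2 * p * p)) / (2.0 * h2 * (q - p));
      if (s <= zi[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zi[k] = s;
    zi[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zi[k + 1] < q) ++k;
    double dq = h * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// Anisotropic Euclidean distance transform: for each true voxel, distance (in
// physical units given by `spacing`) to the nearest false voxel; 0 outside.
// [[Rcpp::export]]
NumericVector cpp_edt3(LogicalVector mask, IntegerVector dims, NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double INF = 1e30;
  std::vector<double> d(n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = mask[i] ? INF : 0.0;
  std::vector<double> f, g;
  // x axis
  f.resize(nx); g.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) f[x] = d[at(x, y, z, nx, ny)];
      dt1d(f, g, nx, spacing[0]);
      for (int x = 0; x < nx; ++x) d[at(x, y, z, nx, ny)] = g[x];
    }
  // y axis
  f.resize(ny); g.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) f[y] = d[at(x, y, z, nx, ny)];
      dt1d(f, g, ny, spacing[1]);
      for (int y = 0; y < ny; ++y) d[at(x, y, z, nx, ny)] = g[y];
    }
  // z axis
  f.resize(nz); g.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) f[z] = d[at(x, y, z, nx, ny)];
      dt1d(f, g, nz, spacing[2]);
      for (int z = 0; z < nz; ++z) d[at(x, y, z, nx, ny)] = g[z];
    }
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(std::max(d[i], 0.0));
  out.attr("dim") = dims;
  return out;
}

// Seeded watershed by priority flood: marker regions grow over `mask` in
// ascending order of `height` (pass -EDT to split at distance ridges).
// [[Rcpp::export]]
IntegerVector cpp_watershed3(NumericVector height, IntegerVector markers,
                             LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  typedef std::pair<double, int> Node; // (height, index)
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  for (R_xlen_t i = 0; i < n; ++i)
    if (markers[i] > 0 && mask[i]) {
      lab[i] = markers[i];
      pq.push(Node(height[i], (int)i));
    }
  while (!pq.empty()) {
    int cur = pq.top().second; pq.pop();
    int z = cur / (nx * ny);
    int rem = cur - z * nx * ny;
    int y = rem / nx;
    int x = rem - y * nx;
    int l = lab[cur];
    for (int dz = -1; dz <= 1; ++dz) {
      int zz = z + dz; if (zz < 0 || zz >= nz) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        int yy = y + dy; if (yy < 0 || yy >= ny) continue;
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          int xx = x + dx; if (xx < 0 || xx >= nx) continue;
          int idx = at(xx, yy, zz, nx, ny);
          if (mask[idx] && lab[idx] == 0) {
            lab[idx] = l;
            pq.push(Node(height[idx], idx));
          }
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
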