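#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Shared helpers for 3D grids stored in R's column-major order:
// linear index i = x + nx*(y + ny*z), 0-based here.

static inline void unravel(R_xlen_t i, int nx, int ny, int &x, int &y, int &z) {
  x = (int)(i % nx);
  R_xlen_t r = i / nx;
  y = (int)(r % ny);
  z = (int)(r / ny);
}

// 6-neighbourhood linear offsets in ascending order: -z, -y, -x, +x, +y, +z.
// Bounds must be checked per-axis by the caller via coordinates.

// [[Rcpp::export(name = ".morph_minmax_cpp")]]
NumericVector morph_minmax_cpp(NumericVector x, IntegerVector dim,
                               IntegerMatrix offsets, bool take_max) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const int k = offsets.nrow();
  NumericVector out(n);
  std::vector<int> ox(k), oy(k), oz(k);
  for (int j = 0; j < k; ++j) { ox[j] = offsets(j,0); oy[j] = offsets(j,1); oz[j] = offsets(j,2); }
  R_xlen_t i = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int xx = 0; xx < nx; ++xx, ++i) {
        double best = take_max ? R_NegInf : R_PosInf;
        for (int j = 0; j < k; ++j) {
          const int qx = xx + ox[j], qy = y + oy[j], qz = z + oz[j];
          if (qx < 0 || qx >= nx || qy < 0 || qy >= ny || qz < 0 || qz >= nz) continue;
          const double v = x[(R_xlen_t)qx + (R_xlen_t)nx * (qy + (R_xlen_t)ny * qz)];
          if (take_max) { if (v > best) best = v; } else { if (v < best) best = v; }
        }
        out[i] = best;
      }
  return out;
}

// Grayscale morphological reconstruction by dilation under a mask image,
// 6-connected, hybrid raster-scan + FIFO queue algorithm (Vincent 1993).
// Exactly equivalent to iterating geodesic dilation with the unit cross
// element until stability; tests assert that equivalence.

// [[Rcpp::export(name = ".reconstruct_cpp")]]
NumericVector reconstruct_cpp(NumericVector marker, NumericVector mask,
                              IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  NumericVector J = clone(marker);

  // forward scan: causal neighbours (-x, -y, -z)
  R_xlen_t i = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++i) {
        double v = J[i];
        if (x > 0 && J[i - sx] > v) v = J[i - sx];
        if (y > 0 && J[i - sy] > v) v = J[i - sy];
        if (z > 0 && J[i - sz] > v) v = J[i - sz];
        if (v > mask[i]) v = mask[i];
        J[i] = v;
      }

  // backward scan + queue seeding
  std::queue<R_xlen_t> fifo;
  i = n - 1;
  for (int z = nz - 1; z >= 0; --z)
    for (int y = ny - 1; y >= 0; --y)
      for (int x = nx - 1; x >= 0; --x, --i) {
        double v = J[i];
        if (x < nx - 1 && J[i + sx] > v) v = J[i + sx];
        if (y < ny - 1 && J[i + sy] > v) v = J[i + sy];
        if (z < nz - 1 && J[i + sz] > v) v = J[i + sz];
        if (v > mask[i]) v = mask[i];
        J[i] = v;
        bool push = false;
        if (x < nx - 1 && J[i + sx] < J[i] && J[i + sx] < mask[i + sx]) push = true;
        else if (y < ny - 1 && J[i + sy] < J[i] && J[i + sy] < mask[i + sy]) push = true;
        else if (z < nz - 1 && J[i + sz] < J[i] && J[i + sz] < mask[i + sz]) push = true;
        if (push) fifo.push(i);
      }

  while (!fifo.empty()) {
    const R_xlen_t p = fifo.front(); fifo.pop();
    int x, y, z; unravel(p, nx, ny, x, y, z);
    const double Jp = J[p];
    const R_xlen_t nbr[6] = { p - sz, p - sy, p - sx, p + sx, p + sy, p + sz };
    const bool ok[6] = { z > 0, y > 0, x > 0, x < nx - 1, y < ny - 1, z < nz - 1 };
    for (int j = 0; j < 6; ++j) {
      if (!ok[j]) continue;
      const R_xlen_t q = nbr[j];
      if (J[q] < Jp && J[q] < mask[q]) {
        J[q] = (Jp < mask[q]) ? Jp : mask[q];
        fifo.push(q);
      }
    }
  }
  return J;
}

// Connected-component labelling (BFS, first-encounter order along the linear
// scan, so labels are deterministic). connectivity: 6 or 26.

// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int> ox, oy, oz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        const int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        ox.push_back(dx); oy.push_back(dy); oz.push_back(dz);
      }
  const int k = (int)ox.size();
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      const R_xlen_t p = stack.back(); stack.pop_back();
      int x, y, z; unravel(p, nx, ny, x, y, z);
      for (int j = 0; j < k; ++j) {
        const int qx = x + ox[j], qy = y + oy[j], qz = z + oz[j];
        if (qx < 0 || qx >= nx || qy < 0 || qy >= ny || qz < 0 || qz >= nz) continue;
        const R_xlen_t q = (R_xlen_t)qx + (R_xlen_t)nx * (qy + (R_xlen_t)ny * qz);
        if (mask[q] && lab[q] == 0) { lab[q] = next; stack.push_back(q); }
      }
    }
  }
  return lab;
}

// Marker-controlled watershed by priority flooding (Meyer) with explicit
// watershed lines (dams). 6-connectivity. Ties in altitude are broken by
// FIFO insertion order; the initial frontier is pushed in linear-index order,
// and neighbours of a processed voxel in ascending linear-offset order
// (-z, -y, -x, +x, +y, +z). A popped voxel whose already-assigned
// 6-neighbours carry two distinct catchment labels becomes a dam (0); one
// whose non-dam neighbours are all dams also becomes a dam, so every voxel
// ends up labelled. markers: 0 = unlabeled, >0 = flooding source label.

struct QItem {
  double prio;
  long long ord;
  R_xlen_t idx;
};
struct QCmp {
  bool operator()(const QItem &a, const QItem &b) const {
    if (a.prio != b.prio) return a.prio > b.prio;
    return a.ord > b.ord;
  }
};

// [[Rcpp::export(name = ".watershed_cpp")]]
IntegerVector watershed_cpp(NumericVector grad, IntegerVector markers,
                            IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  const int DAM = -1;
  IntegerVector lab = clone(markers);
  std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
  long long counter = 0;

  // 32-bit float quantisation of altitudes for platform-stable ordering
  std::vector<float> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = (float)grad[i];

  for (R_xlen_t i = 0; i < n; ++i) {
    if (lab[i] != 0) continue;
    int x, y, z; unravel(i, nx, ny, x, y, z);
    const R_xlen_t nbr[6] = { i - sz, i - sy, i - sx, i + sx, i + sy, i + sz };
    const bool ok[6] = { z > 0, y > 0, x > 0, x < nx - 1, y < ny - 1, z < nz - 1 };
    bool border = false;
    for (int j = 0; j < 6 && !border; ++j)
      if (ok[j] && lab[nbr[j]] > 0) border = true;
    if (border) pq.push({ (double)g[i], counter++, i });
  }

  while (!pq.empty()) {
    const QItem it = pq.top(); pq.pop();
    const R_xlen_t p = it.idx;
    if (lab[p] != 0) continue;
    int x, y, z; unravel(p, nx, ny, x, y, z);
    const R_xlen_t nbr[6] = { p - sz, p - sy, p - sx, p + sx, p + sy, p + sz };
    const bool ok[6] = { z > 0, y > 0, x > 0, x < nx - 1, y < ny - 1, z < nz - 1 };
    int found = 0;
    for (int j = 0; j < 6; ++j) {
      if (!ok[j]) continue;
      const int lq = lab[nbr[j]];
      if (lq > 0) {
        if (found == 0) found = lq;
        else if (found != lq) { found = DAM; break; }
      }
    }
    lab[p] = (found == 0) ? DAM : found;
    for (int j = 0; j < 6; ++j) {
      if (!ok[j]) continue;
      const R_xlen_t q = nbr[j];
      if (lab[q] == 0) pq.push({ (double)g[q], counter++, q });
    }
  }
  for (R_xlen_t i = 0; i < n; ++i) if (lab[i] == DAM) lab[i] = 0;
  return lab;
}

// Separable 3D box-mean filter; windows are truncated at the grid faces and
// normalised by the in-bounds count, so constants are preserved.

static void boxmean_axis(std::vector<double> &a, int nx, int ny, int nz,
                         int axis, int r) {
  if (r <= 0) return;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  R_xlen_t stride; int len, n1, n2; R_xlen_t s1, s2;
  if (axis == 0)      { stride = sx; len = nx; n1 = ny; n2 = nz; s1 = sy; s2 = sz; }
  else if (axis == 1) { stride = sy; len = ny; n1 = nx; n2 = nz; s1 = sx; s2 = sz; }
  else                { stride = sz; len = nz; n1 = nx; n2 = ny; s1 = sx; s2 = sy; }
  std::vector<double> cum((size_t)len + 1), line((size_t)len);
  for (int j2 = 0; j2 < n2; ++j2)
    for (int j1 = 0; j1 < n1; ++j1) {
      const R_xlen_t base = s1 * j1 + s2 * j2;
      cum[0] = 0.0;
      for (int t = 0; t < len; ++t) cum[t + 1] = cum[t] + a[base + stride * t];
      for (int t = 0; t < len; ++t) {
        const int lo = std::max(0, t - r), hi = std::min(len - 1, t + r);
        line[t] = (cum[hi + 1] - cum[lo]) / (hi - lo + 1);
      }
      for (int t = 0; t < len; ++t) a[base + stride * t] = line[t];
    }
}

// [[Rcpp::export(name = ".boxmean_cpp")]]
NumericVector boxmean_cpp(NumericVector x, IntegerVector dim, IntegerVector radius) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> a(x.begin(), x.end());
  boxmean_axis(a, nx, ny, nz, 0, radius[0]);
  boxmean_axis(a, nx, ny, nz, 1, radius[1]);
  boxmean_axis(a, nx, ny, nz, 2, radius[2]);
  return NumericVector(a.begin(), a.end());
}
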