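#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <queue>
#include <vector>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------------------
// Euclidean distance transform, Felzenszwalb & Huttenlocher lower-envelope
// form, applied separably along each axis with physical spacing. Tracks the
// nearest-site linear index so the same pass yields a feature transform.
// ---------------------------------------------------------------------------

// One 1-D pass. f holds squared distances so far (INF where no site reaches),
// site the provisional nearest-site index (-1 where none). w is the spacing
// along this axis. Results land in d / dsite.
static void dt1d(const std::vector<double>& f, const std::vector<int>& site,
                 int n, double w,
                 std::vector<double>& d, std::vector<int>& dsite,
                 std::vector<int>& v, std::vector<double>& z) {
  int first = -1;
  for (int q = 0; q < n; ++q)
    if (f[q] < INF) { first = q; break; }
  if (first < 0) {
    for (int q = 0; q < n; ++q) { d[q] = INF; dsite[q] = -1; }
    return;
  }
  const double w2 = w * w;
  int k = 0;
  v[0] = first;
  z[0] = -INF;
  z[1] = INF;
  for (int q = first + 1; q < n; ++q) {
    if (f[q] == INF) continue;
    while (true) {
      int p = v[k];
      double s = ((f[q] + (double)q * q * w2) - (f[p] + (double)p * p * w2)) /
                 (2.0 * w2 * (q - p));
      if (s <= z[k] && k > 0) {
        --k;
      } else {
        if (s <= z[k]) { // k == 0: replace
          v[0] = q; z[0] = -INF; z[1] = INF;
        } else {
          ++k; v[k] = q; z[k] = s; z[k + 1] = INF;
        }
        break;
      }
    }
  }
  int kk = 0;
  for (int q = 0; q < n; ++q) {
    while (z[kk + 1] < q) ++kk;
    int p = v[kk];
    double dq = (double)(q - p) * w;
    d[q] = dq * dq + f[p];
    dsite[q] = site[p];
  }
}

// [[Rcpp::export]]
List cpp_edt(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector dist2(n);
  IntegerVector nearest(n);
  std::vector<double> D((size_t)n);
  std::vector<int> S((size_t)n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (mask[i]) { D[i] = 0.0; S[i] = (int)i; }
    else { D[i] = INF; S[i] = -1; }
  }
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> site(nmax), dsite(nmax), v(nmax);

  // pass along x
  for (int kzi = 0; kzi < nz; ++kzi)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)kzi * nx * ny + (R_xlen_t)j * nx;
      for (int i = 0; i < nx; ++i) { f[i] = D[base + i]; site[i] = S[base + i]; }
      dt1d(f, site, nx, spacing[0], d, dsite, v, z);
      for (int i = 0; i < nx; ++i) { D[base + i] = d[i]; S[base + i] = dsite[i]; }
    }
  // pass along y
  for (int kzi = 0; kzi < nz; ++kzi)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)kzi * nx * ny + i;
      for (int j = 0; j < ny; ++j) { f[j] = D[base + (R_xlen_t)j * nx]; site[j] = S[base + (R_xlen_t)j * nx]; }
      dt1d(f, site, ny, spacing[1], d, dsite, v, z);
      for (int j = 0; j < ny; ++j) { D[base + (R_xlen_t)j * nx] = d[j]; S[base + (R_xlen_t)j * nx] = dsite[j]; }
    }
  // pass along z
  R_xlen_t stride = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)j * nx + i;
      for (int kzi = 0; kzi < nz; ++kzi) { f[kzi] = D[base + kzi * stride]; site[kzi] = S[base + kzi * stride]; }
      dt1d(f, site, nz, spacing[2], d, dsite, v, z);
      for (int kzi = 0; kzi < nz; ++kzi) { D[base + kzi * stride] = d[kzi]; S[base + kzi * stride] = dsite[kzi]; }
    }

  for (R_xlen_t i = 0; i < n; ++i) {
    dist2[i] = D[i];
    nearest[i] = (S[i] < 0) ? NA_INTEGER : S[i] + 1; // 1-based for R
  }
  return List::create(_["dist2"] = dist2, _["nearest"] = nearest);
}

// ---------------------------------------------------------------------------
// First-order upwind (Godunov) fast marching on an axis-aligned grid with
// anisotropic spacing. Solves |grad T| * F = 1 from a single seed voxel.
// ---------------------------------------------------------------------------

struct HeapNode {
  double t;
  R_xlen_t idx;
  bool operator>(const HeapNode& o) const {
    if (t != o.t) return t > o.t;
    return idx > o.idx; // deterministic tie order
  }
};

// Solve the upwind quadratic given per-axis upwind values ta (INF if none)
static double eikonal_update(const double ta[3], const double h[3], double invF) {
  // sort axes by ta ascending
  int ord[3] = {0, 1, 2};
  for (int a = 0; a < 2; ++a)
    for (int b = a + 1; b < 3; ++b)
      if (ta[ord[b]] < ta[ord[a]]) std::swap(ord[a], ord[b]);
  double best = INF;
  double sa = 0.0, sb = 0.0, sc = -invF * invF; // sum 1/h^2, -2 ta/h^2, ta^2/h^2
  for (int m = 0; m < 3; ++m) {
    int a = ord[m];
    if (!(ta[a] < INF)) break;
    double ih2 = 1.0 / (h[a] * h[a]);
    sa += ih2;
    sb += -2.0 * ta[a] * ih2;
    sc += ta[a] * ta[a] * ih2;
    double disc = sb * sb - 4.0 * sa * sc;
    if (disc < 0) continue;
    double t = (-sb + std::sqrt(disc)) / (2.0 * sa);
    // t must exceed every ta used
    if (t >= ta[a]) best = t;
  }
  if (!(best < INF)) {
    // fall back to 1-D update from the smallest ta
    int a = ord[0];
    if (ta[a] < INF) best = ta[a] + h[a] * invF;
  }
  return best;
}

// [[Rcpp::export]]
NumericVector cpp_fast_march(NumericVector speed, IntegerVector dim,
                             NumericVector spacing, double seed_idx1) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  R_xlen_t seed = (R_xlen_t)seed_idx1 - 1;
  if (seed < 0 || seed >= n) stop("seed index out of range");
  NumericVector T(n, INF);
  std::vector<char> state((size_t)n, 0); // 0 far, 1 trial, 2 accepted
  std::priority_queue<HeapNode, std::vector<HeapNode>, std::greater<HeapNode> > heap;
  const double h[3] = {spacing[0], spacing[1], spacing[2]};
  const R_xlen_t stridey = nx, stridez = (R_xlen_t)nx * ny;

  T[seed] = 0.0;
  heap.push({0.0, seed});
  state[seed] = 1;

  while (!heap.empty()) {
    HeapNode top = heap.top();
    heap.pop();
    R_xlen_t c = top.idx;
    if (state[c] == 2) continue;
    if (top.t > T[c]) continue; // stale entry
    state[c] = 2;
    int ci = (int)(c % nx);
    int cj = (int)((c / nx) % ny);
    int ck = (int)(c / stridez);
    const int di[6] = {-1, 1, 0, 0, 0, 0};
    const int dj[6] = {0, 0, -1, 1, 0, 0};
    const int dk[6] = {0, 0, 0, 0, -1, 1};
    for (int m = 0; m < 6; ++m) {
      int i = ci + di[m], j = cj + dj[m], k = ck + dk[m];
      if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) continue;
      R_xlen_t q = (R_xlen_t)k * stridez + (R_xlen_t)j * stridey + i;
      if (state[q] == 2) continue;
      double F = speed[q];
      if (!(F > 0)) continue; // unreachable through zero speed
      double ta[3];
      // upwind neighbor values per axis
      int qi = i, qj = j, qk = k;
      double tminx = INF, tminy = INF, tminz = INF;
      if (qi > 0) { R_xlen_t p = q - 1; if (state[p] == 2) tminx = T[p]; }
      if (qi < nx - 1) { R_xlen_t p = q + 1; if (state[p] == 2 && T[p] < tminx) tminx = T[p]; }
      if (qj > 0) { R_xlen_t p = q - stridey; if (state[p] == 2) tminy = T[p]; }
      if (qj < ny - 1) { R_xlen_t p = q + stridey; if (state[p] == 2 && T[p] < tminy) tminy = T[p]; }
      if (qk > 0) { R_xlen_t p = q - stridez; if (state[p] == 2) tminz = T[p]; }
      if (qk < nz - 1) { R_xlen_t p = q + stridez; if (state[p] == 2 && T[p] < tminz) tminz = T[p]; }
      ta[0] = tminx; ta[1] = tminy; ta[2] = tminz;
      double tnew = eikonal_update(ta, h, 1.0 / F);
      if (tnew < T[q]) {
        T[q] = tnew;
        state[q] = 1;
        heap.push({tnew, q});
      }
    }
  }
  return T;
}

// ---------------------------------------------------------------------------
// Mark voxels within radius (mm) of any of a set of world-space points.
// Used by the tracer's coverage bookkeeping. Returns an updated copy.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
LogicalVector cpp_cover_points(LogicalVector covered, NumericMatrix pts,
                               NumericVector radius, IntegerVector dim,
                               NumericVector spacing, NumericVector origin) {
  LogicalVector out = clone(covered);
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t stridez = (R_xlen_t)nx * ny;
  for (int p = 0; p < pts.nrow(); ++p) {
    double r = radius[p % radius.size()];
    double r2 = r * r;
    double wx = pts(p, 0), wy = pts(p, 1), wz = pts(p, 2);
    // continuous 0-based index of the point
    double cx = (wx - origin[0]) / spacing[0];
    double cy = (wy - origin[1]) / spacing[1];
    double cz = (wz - origin[2]) / spacing[2];
    int i0 = std::max(0, (int)std::ceil(cx - r / spacing[0]));
    int i1 = std::min(nx - 1, (int)std::floor(cx + r / spacing[0]));
    int j0 = std::max(0, (int)std::ceil(cy - r / spacing[1]));
    int j1 = std::min(ny - 1, (int)std::floor(cy + r / spacing[1]));
    int k0 = std::max(0, (int)std::ceil(cz - r / spacing[2]));
    int k1 = std::min(nz - 1, (int)std::floor(cz + r / spacing[2]));
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i) {
          double dx = (i - cx) * spacing[0];
          double dy = (j - cy) * spacing[1];
          double dz = (k - cz) * spacing[2];
          if (dx * dx + dy * dy + dz * dz <= r2)
            out[(R_xlen_t)k * stridez + (R_xlen_t)j * nx + i] = true;
        }
  }
  return out;
}
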