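// 3D voxel kernels: anisotropic EDT, topology-preserving thinning,
// marker-controlled watershed, connected components, phantom rasterization.
// Array layout everywhere: R array with dim = c(nz, ny, nx), column-major,
// linear index = iz + nz*(iy + ny*ix); spacing = (dz, dy, dx) in micrometres;
// the physical centre of voxel (iz,iy,ix) (0-based) is ((ix+.5)dx,(iy+.5)dy,(iz+.5)dz).
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------------------
// Squared Euclidean distance transform (Felzenszwalb & Huttenlocher 2012),
// separable per axis, with per-axis sample spacing. Returns for every voxel
// the squared distance (um^2) to the nearest TRUE voxel; Inf if none.
// ---------------------------------------------------------------------------
static void dt1d(std::vector<double>& f, std::vector<double>& d, double w) {
  int n = (int)f.size();
  double w2 = w * w;
  // lower envelope over parabolas with finite base value only
  std::vector<int> fin;
  for (int q = 0; q < n; q++) if (f[q] < INF) fin.push_back(q);
  if (fin.empty()) { for (int q = 0; q < n; q++) d[q] = INF; return; }
  std::vector<int> v(fin.size());
  std::vector<double> z(fin.size() + 1);
  int k = 0;
  v[0] = fin[0]; z[0] = -INF; z[1] = INF;
  for (size_t qi = 1; qi < fin.size(); qi++) {
    int q = fin[qi];
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + w2 * (double)q * q) - (f[p] + w2 * (double)p * p)) / (2.0 * w2 * (q - p));
      if (s <= z[k] && k > 0) k--; else break;
    }
    if (s <= z[k]) { v[k] = q; }  // k == 0 and new parabola dominates
    else { k++; v[k] = q; z[k] = s; }
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    int p = v[k];
    d[q] = w2 * (double)(q - p) * (q - p) + f[p];
  }
}

// [[Rcpp::export]]
NumericVector cpp_sqdist_to_true(LogicalVector mask, IntegerVector dims, NumericVector spacing) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = mask[i] ? 0.0 : INF;
  // pass along z (stride 1), then y (stride nz), then x (stride nz*ny)
  std::vector<double> f, d;
  // z
  f.resize(nz); d.resize(nz);
  for (int ix = 0; ix < nx; ix++) for (int iy = 0; iy < ny; iy++) {
    R_xlen_t base = (R_xlen_t)nz * (iy + (R_xlen_t)ny * ix);
    for (int iz = 0; iz < nz; iz++) f[iz] = out[base + iz];
    dt1d(f, d, spacing[0]);
    for (int iz = 0; iz < nz; iz++) out[base + iz] = d[iz];
  }
  // y
  f.resize(ny); d.resize(ny);
  for (int ix = 0; ix < nx; ix++) for (int iz = 0; iz < nz; iz++) {
    R_xlen_t base = iz + (R_xlen_t)nz * ny * ix;
    for (int iy = 0; iy < ny; iy++) f[iy] = out[base + (R_xlen_t)nz * iy];
    dt1d(f, d, spacing[1]);
    for (int iy = 0; iy < ny; iy++) out[base + (R_xlen_t)nz * iy] = d[iy];
  }
  // x
  f.resize(nx); d.resize(nx);
  for (int iy = 0; iy < ny; iy++) for (int iz = 0; iz < nz; iz++) {
    R_xlen_t base = iz + (R_xlen_t)nz * iy;
    R_xlen_t stride = (R_xlen_t)nz * ny;
    for (int ix = 0; ix < nx; ix++) f[ix] = out[base + stride * ix];
    dt1d(f, d, spacing[2]);
    for (int ix = 0; ix < nx; ix++) out[base + stride * ix] = d[ix];
  }
  return out;
}

// ---------------------------------------------------------------------------
// 26-connected (or 6-connected) component labelling, BFS.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims, int connectivity) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; s++) {
    if (!mask[s] || lab[s] != 0) continue;
    next++;
    lab[s] = next;
    stack.clear(); stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int iz = (int)(cur % nz);
      int iy = (int)((cur / nz) % ny);
      int ix = (int)(cur / ((R_xlen_t)nz * ny));
      for (int dx = -1; dx <= 1; dx++) for (int dy = -1; dy <= 1; dy++) for (int dz = -1; dz <= 1; dz++) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        if (connectivity == 6 && (std::abs(dx) + std::abs(dy) + std::abs(dz)) != 1) continue;
        int jx = ix + dx, jy = iy + dy, jz = iz + dz;
        if (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 || jz >= nz) continue;
        R_xlen_t j = jz + (R_xlen_t)nz * (jy + (R_xlen_t)ny * jx);
        if (mask[j] && lab[j] == 0) { lab[j] = next; stack.push_back(j); }
      }
    }
  }
  return lab;
}

// [[Rcpp::export]]
IntegerVector cpp_neighbor_count26(LogicalVector mask, IntegerVector dims) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector cnt(n, 0);
  for (R_xlen_t s = 0; s < n; s++) {
    if (!mask[s]) { cnt[s] = NA_INTEGER; continue; }
    int iz = (int)(s % nz), iy = (int)((s / nz) % ny), ix = (int)(s / ((R_xlen_t)nz * ny));
    int c = 0;
    for (int dx = -1; dx <= 1; dx++) for (int dy = -1; dy <= 1; dy++) for (int dz = -1; dz <= 1; dz++) {
      if (dx == 0 && dy == 0 && dz == 0) continue;
      int jx = ix + dx, jy = iy + dy, jz = iz + dz;
      if (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 || jz >= nz) continue;
      if (mask[jz + (R_xlen_t)nz * (jy + (R_xlen_t)ny * jx)]) c++;
    }
    cnt[s] = c;
  }
  return cnt;
}

// ---------------------------------------------------------------------------
// Simple-point test (Bertrand & Malandain characterization):
// a foreground voxel is simple iff (a) its 26-neighbourhood contains exactly
// one 26-connected foreground component, and (b) the background voxels of its
// 18-neighbourhood contain exactly one 6-connected component that is
// 6-adjacent to the centre.
// ---------------------------------------------------------------------------
static inline int off_idx(int dz, int dy, int dx) { return (dz + 1) + 3 * ((dy + 1) + 3 * (dx + 1)); }

static int count_fg26(const bool nb[27]) {
  int lab[27]; for (int i = 0; i < 27; i++) lab[i] = 0;
  int ncomp = 0, stack[27], sp;
  for (int i = 0; i < 27; i++) {
    if (i == 13 || !nb[i] || lab[i]) continue;
    ncomp++; lab[i] = ncomp; sp = 0; stack[sp++] = i;
    while (sp > 0) {
      int c = stack[--sp];
      int cz = c % 3 - 1, cy = (c / 3) % 3 - 1, cx = c / 9 - 1;
      for (int dx = -1; dx <= 1; dx++) for (int dy = -1; dy <= 1; dy++) for (int dz = -1; dz <= 1; dz++) {
        int jz = cz + dz, jy = cy + dy, jx = cx + dx;
        if (jz < -1 || jz > 1 || jy < -1 || jy > 1 || jx < -1 || jx > 1) continue;
        int j = off_idx(jz, jy, jx);
        if (j == 13 || j == c || !nb[j] || lab[j]) continue;
        lab[j] = ncomp; stack[sp++] = j;
      }
    }
  }
  return ncomp;
}

static int count_bg6_18(const bool nb[27]) {
  // positions of the 18-neighbourhood: offsets with at least one zero coordinate
  int lab[27]; for (int i = 0; i < 27; i++) lab[i] = 0;
  int ncomp = 0, stack[27], sp;
  const int faces[6] = { off_idx(-1,0,0), off_idx(1,0,0), off_idx(0,-1,0),
                         off_idx(0,1,0), off_idx(0,0,-1), off_idx(0,0,1) };
  for (int fi = 0; fi < 6; fi++) {
    int seed = faces[fi];
    if (nb[seed] || lab[seed]) continue;  // must be background and unlabelled
    ncomp++; lab[seed] = ncomp; sp = 0; stack[sp++] = seed;
    while (sp > 0) {
      int c = stack[--sp];
      int cz = c % 3 - 1, cy = (c / 3) % 3 - 1, cx = c / 9 - 1;
      const int d6[6][3] = { {1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1} };
      for (int k = 0; k < 6; k++) {
        int jz = cz + d6[k][0], jy = cy + d6[k][1], jx = cx + d6[k][2];
        if (jz < -1 || jz > 1 || jy < -1 || jy > 1 || jx < -1 || jx > 1) continue;
        if ((jz != 0) && (jy != 0) && (jx != 0)) continue;  // stay in N18
        int j = off_idx(jz, jy, jx);
        if (j == 13 || nb[j] || lab[j]) continue;
        lab[j] = ncomp; stack[sp++] = j;
      }
    }
  }
  return ncomp;
}

static inline void fill_nb(const std::vector<char>& m, int nz, int ny, int nx,
                           int iz, int iy, int ix, bool nb[27]) {
  for (int dx = -1; dx <= 1; dx++) for (int dy = -1; dy <= 1; dy++) for (int dz = -1; dz <= 1; dz++) {
    int jz = iz + dz, jy = iy + dy, jx = ix + dx;
    bool v = false;
    if (jz >= 0 && jz < nz && jy >= 0 && jy < ny && jx >= 0 && jx < nx)
      v = m[jz + (R_xlen_t)nz * (jy + (R_xlen_t)ny * jx)] != 0;
    nb[off_idx(dz, dy, dx)] = v;
  }
}

static inline bool is_simple(const bool nb[27]) {
  return count_fg26(nb) == 1 && count_bg6_18(nb) == 1;
}

static inline int fg_degree(const bool nb[27]) {
  int c = 0; for (int i = 0; i < 27; i++) if (i != 13 && nb[i]) c++;
  return c;
}

// ---------------------------------------------------------------------------
// 3D curve thinning: iterative removal of simple, non-endpoint border voxels
// in six directional sub-iterations until stable, with sequential recheck
// inside each sub-iteration. Endpoints (exactly one 26-neighbour) are
// preserved so curve geometry survives.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
LogicalVector cpp_thin3d(LogicalVector mask, IntegerVector dims) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<char> m(n);
  for (R_xlen_t i = 0; i < n; i++) m[i] = mask[i] ? 1 : 0;
  // direction offsets (dz,dy,dx): U D N S E W
  const int dir[6][3] = { {1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1} };
  bool nb[27];
  std::vector<R_xlen_t> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; d++) {
      cand.clear();
      for (R_xlen_t s = 0; s < n; s++) {
        if (!m[s]) continue;
        int iz = (int)(s % nz), iy = (int)((s / nz) % ny), ix = (int)(s / ((R_xlen_t)nz * ny));
        int jz = iz + dir[d][0], jy = iy + dir[d][1], jx = ix + dir[d][2];
        bool bg = true;
        if (jz >= 0 && jz < nz && jy >= 0 && jy < ny && jx >= 0 && jx < nx)
          bg = m[jz + (R_xlen_t)nz * (jy + (R_xlen_t)ny * jx)] == 0;
        if (!bg) continue;
        fill_nb(m, nz, ny, nx, iz, iy, ix, nb);
        int deg = fg_degree(nb);
        if (deg <= 1) continue;        // endpoint / isolated: keep
        if (is_simple(nb)) cand.push_back(s);
      }
      // sequential re-checked deletion (candidates were computed in parallel)
      for (size_t c = 0; c < cand.size(); c++) {
        R_xlen_t s = cand[c];
        int iz = (int)(s % nz), iy = (int)((s / nz) % ny), ix = (int)(s / ((R_xlen_t)nz * ny));
        fill_nb(m, nz, ny, nx, iz, iy, ix, nb);
        if (fg_degree(nb) <= 1) continue;
        if (is_simple(nb)) { m[s] = 0; changed = true; }
      }
    }
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = m[i] != 0;
  return out;
}

// ---------------------------------------------------------------------------
// Marker-controlled watershed by priority flooding of a relief (ascending).
// Seeds are pushed in increasing marker id order; equal-relief ties resolve
// by insertion order, so the flood is fully deterministic.
// ---------------------------------------------------------------------------
struct QEntry {
  double relief; unsigned long order; R_xlen_t idx; int lab;
};
struct QCmp {
  bool operator()(const QEntry& a, const QEntry& b) const {
    if (a.relief != b.relief) return a.relief > b.relief;  // min-heap on relief
    return a.order > b.order;
  }
};

// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector relief, IntegerVector markers,
                            LogicalVector mask, IntegerVector dims) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n, 0);
  std::priority_queue<QEntry, std::vector<QEntry>, QCmp> pq;
  unsigned long ord = 0;
  // seed in increasing marker id order
  int maxm = 0;
  for (R_xlen_t i = 0; i < n; i++) if (markers[i] > maxm) maxm = markers[i];
  for (int mlab = 1; mlab <= maxm; mlab++) {
    for (R_xlen_t i = 0; i < n; i++) {
      if (markers[i] == mlab && mask[i]) {
        lab[i] = mlab;
        pq.push(QEntry{ relief[i], ord++, i, mlab });
      }
    }
  }
  while (!pq.empty()) {
    QEntry e = pq.top(); pq.pop();
    R_xlen_t s = e.idx;
    int iz = (int)(s % nz), iy = (int)((s / nz) % ny), ix = (int)(s / ((R_xlen_t)nz * ny));
    for (int dx = -1; dx <= 1; dx++) for (int dy = -1; dy <= 1; dy++) for (int dz = -1; dz <= 1; dz++) {
      if (dx == 0 && dy == 0 && dz == 0) continue;
      int jx = ix + dx, jy = iy + dy, jz = iz + dz;
      if (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 || jz >= nz) continue;
      R_xlen_t j = jz + (R_xlen_t)nz * (jy + (R_xlen_t)ny * jx);
      if (!mask[j] || lab[j] != 0) continue;
      lab[j] = lab[s];
      pq.push(QEntry{ relief[j], ord++, j, lab[j] });
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Phantom rasterization: capsules (tapered tubes) and ellipsoids drawn into
// the intensity volume with max blending; physical coordinates in um.
// pts: k x 3 matrix of polyline points (x,y,z); radii: k radii.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
void cpp_draw_polyline(NumericVector vol, IntegerVector dims, NumericVector spacing,
                       NumericMatrix pts, NumericVector radii, double value) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  double dz = spacing[0], dy = spacing[1], dx = spacing[2];
  int k = pts.nrow();
  for (int seg = 0; seg + 1 < k; seg++) {
    double x0 = pts(seg, 0), y0 = pts(seg, 1), z0 = pts(seg, 2);
    double x1 = pts(seg + 1, 0), y1 = pts(seg + 1, 1), z1 = pts(seg + 1, 2);
    double r0 = radii[seg], r1 = radii[seg + 1];
    double rmax = std::max(r0, r1);
    int ix0 = std::max(0, (int)std::floor((std::min(x0, x1) - rmax) / dx - 0.5));
    int ix1 = std::min(nx - 1, (int)std::ceil((std::max(x0, x1) + rmax) / dx));
    int iy0 = std::max(0, (int)std::floor((std::min(y0, y1) - rmax) / dy - 0.5));
    int iy1 = std::min(ny - 1, (int)std::ceil((std::max(y0, y1) + rmax) / dy));
    int iz0 = std::max(0, (int)std::floor((std::min(z0, z1) - rmax) / dz - 0.5));
    int iz1 = std::min(nz - 1, (int)std::ceil((std::max(z0, z1) + rmax) / dz));
    double vx = x1 - x0, vy = y1 - y0, vz = z1 - z0;
    double vv = vx * vx + vy * vy + vz * vz;
    for (int ix = ix0; ix <= ix1; ix++) for (int iy = iy0; iy <= iy1; iy++) for (int iz = iz0; iz <= iz1; iz++) {
      double px = (ix + 0.5) * dx, py = (iy + 0.5) * dy, pz = (iz + 0.5) * dz;
      double t = 0.0;
      if (vv > 0) {
        t = ((px - x0) * vx + (py - y0) * vy + (pz - z0) * vz) / vv;
        t = std::max(0.0, std::min(1.0, t));
      }
      double cx = x0 + t * vx, cy = y0 + t * vy, cz = z0 + t * vz;
      double r = r0 + t * (r1 - r0);
      double d2 = (px - cx) * (px - cx) + (py - cy) * (py - cy) + (pz - cz) * (pz - cz);
      if (d2 <= r * r) {
        R_xlen_t s = iz + (R_xlen_t)nz * (iy + (R_xlen_t)ny * ix);
        if (value > vol[s]) vol[s] = value;
      }
    }
  }
}

// [[Rcpp::export]]
void cpp_draw_ellipsoid(NumericVector vol, IntegerVector dims, NumericVector spacing,
                        NumericVector center, NumericVector semi, double value) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  double dz = spacing[0], dy = spacing[1], dx = spacing[2];
  double cx = center[0], cy = center[1], cz = center[2];
  double ax = semi[0], ay = semi[1], az = semi[2];
  int ix0 = std::max(0, (int)std::floor((cx - ax) / dx - 0.5));
  int ix1 = std::min(nx - 1, (int)std::ceil((cx + ax) / dx));
  int iy0 = std::max(0, (int)std::floor((cy - ay) / dy - 0.5));
  int iy1 = std::min(ny - 1, (int)std::ceil((cy + ay) / dy));
  int iz0 = std::max(0, (int)std::floor((cz - az) / dz - 0.5));
  int iz1 = std::min(nz - 1, (int)std::ceil((cz + az) / dz));
  for (int ix = ix0; ix <= ix1; ix++) for (int iy = iy0; iy <= iy1; iy++) for (int iz = iz0; iz <= iz1; iz++) {
    double px = (ix + 0.5) * dx, py = (iy + 0.5) * dy, pz = (iz + 0.5) * dz;
    double q = ((px - cx) / ax) * ((px - cx) / ax) + ((py - cy) / ay) * ((py - cy) / ay)
             + ((pz - cz) / az) * ((pz - cz) / az);
    if (q <= 1.0) {
      R_xlen_t s = iz + (R_xlen_t)nz * (iy + (R_xlen_t)ny * ix);
      if (value > vol[s]) vol[s] = value;
    }
  }
}

// Separable Gaussian blur, sigma given in voxels per axis (z,y,x); kernels
// truncated at 3 sigma and renormalized at the borders.
static void blur_axis(std::vector<double>& v, std::vector<double>& tmp,
                      int nz, int ny, int nx, int axis, double sigma) {
  if (sigma <= 0) return;
  int rad = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> ker(2 * rad + 1);
  for (int i = -rad; i <= rad; i++) ker[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
  int len = (axis == 0) ? nz : (axis == 1) ? ny : nx;
  R_xlen_t stride = (axis == 0) ? 1 : (axis == 1) ? (R_xlen_t)nz : (R_xlen_t)nz * ny;
  int n1 = (axis == 0) ? ny : nz;
  int n2 = (axis == 2) ? ny : nx;
  for (int a = 0; a < n1; a++) for (int b = 0; b < n2; b++) {
    R_xlen_t base;
    if (axis == 0)      base = (R_xlen_t)nz * (a + (R_xlen_t)ny * b);
    else if (axis == 1) base = a + (R_xlen_t)nz * ny * b;
    else                base = a + (R_xlen_t)nz * b;
    for (int i = 0; i < len; i++) {
      double acc = 0, wsum = 0;
      for (int k = -rad; k <= rad; k++) {
        int j = i + k;
        if (j < 0 || j >= len) continue;
        acc += ker[k + rad] * v[base + stride * j];
        wsum += ker[k + rad];
      }
      tmp[base + stride * i] = acc / wsum;
    }
    for (int i = 0; i < len; i++) v[base + stride * i] = tmp[base + stride * i];
  }
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_blur3d(NumericVector vol, IntegerVector dims, NumericVector sigma_vox) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<double> v(n), tmp(n);
  for (R_xlen_t i = 0; i < n; i++) v[i] = vol[i];
  blur_axis(v, tmp, nz, ny, nx, 0, sigma_vox[0]);
  blur_axis(v, tmp, nz, ny, nx, 1, sigma_vox[1]);
  blur_axis(v, tmp, nz, ny, nx, 2, sigma_vox[2]);
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = v[i];
  return out;
}

// Local mean and sd in a disk of radius r pixels, per 2D slice (rows x cols
// matrix), direct accumulation. Used by the Phansalkar local threshold.
// [[Rcpp::export]]
List cpp_disk_mean_sd(NumericMatrix img, int radius) {
  int nr = img.nrow(), nc = img.ncol();
  // precompute disk offsets
  std::vector<int> offr, offc;
  for (int a = -radius; a <= radius; a++) for (int b = -radius; b <= radius; b++)
    if (a * a + b * b <= radius * radius) { offr.push_back(a); offc.push_back(b); }
  int m = (int)offr.size();
  NumericMatrix mu(nr, nc), sd(nr, nc);
  for (int j = 0; j < nc; j++) for (int i = 0; i < nr; i++) {
    double s = 0, s2 = 0; int cnt = 0;
    for (int k = 0; k < m; k++) {
      int r = i + offr[k], c = j + offc[k];
      if (r < 0 || r >= nr || c < 0 || c >= nc) continue;
      double v = img(r, c);
      s += v; s2 += v * v; cnt++;
    }
    double mean = s / cnt;
    double var = s2 / cnt - mean * mean;
    mu(i, j) = mean;
    sd(i, j) = var > 0 ? std::sqrt(var) : 0.0;
  }
  return List::create(_["mean"] = mu, _["sd"] = sd);
}
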