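#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------------------
// 1D squared distance transform (lower envelope of parabolas) on a sampled
// line with grid step h.  Positions are x_i = i * h.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, double h) {
  int n = (int)f.size();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF && f[v[k]] == INF) { // skip empty parabolas
      continue;
    }
    double xq = q * h;
    double s = INF;
    while (k >= 0) {
      double xv = v[k] * h;
      if (f[v[k]] == INF) { s = -INF; }
      else if (f[q] == INF) { s = INF; }
      else {
        s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * xq - 2.0 * xv);
      }
      if (s <= z[k]) { --k; } else break;
    }
    if (k < 0) {
      k = 0;
      v[0] = q;
      z[0] = -INF;
      z[1] = INF;
    } else {
      ++k;
      v[k] = q;
      z[k] = s;
      z[k + 1] = INF;
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * h;
    while (z[k + 1] < xq) ++k;
    double xv = v[k] * h;
    d[q] = (f[v[k]] == INF) ? INF : (xq - xv) * (xq - xv) + f[v[k]];
  }
}

// Spacing-aware squared Euclidean distance transform: for each nonzero voxel,
// squared distance (mm^2) to the nearest zero voxel. Zero voxels map to 0.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(IntegerVector mask, IntegerVector dim,
                         NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector D(n);
  for (R_xlen_t i = 0; i < n; ++i) D[i] = mask[i] ? INF : 0.0;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)j * nx + (R_xlen_t)k * nx * ny;
      f.assign(nx, 0.0);
      for (int i = 0; i < nx; ++i) f[i] = D[base + i];
      d.assign(nx, 0.0);
      dt1d(f, d, v, z, spacing[0]);
      for (int i = 0; i < nx; ++i) D[base + i] = d[i];
    }
  // axis y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)i + (R_xlen_t)k * nx * ny;
      f.assign(ny, 0.0);
      for (int j = 0; j < ny; ++j) f[j] = D[base + (R_xlen_t)j * nx];
      d.assign(ny, 0.0);
      dt1d(f, d, v, z, spacing[1]);
      for (int j = 0; j < ny; ++j) D[base + (R_xlen_t)j * nx] = d[j];
    }
  // axis z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)i + (R_xlen_t)j * nx;
      f.assign(nz, 0.0);
      for (int k = 0; k < nz; ++k) f[k] = D[base + (R_xlen_t)k * nx * ny];
      d.assign(nz, 0.0);
      dt1d(f, d, v, z, spacing[2]);
      for (int k = 0; k < nz; ++k) D[base + (R_xlen_t)k * nx * ny] = d[k];
    }
  return D;
}

static void neighbor_offsets(int connectivity, int nx, int ny,
                             std::vector<int>& di, std::vector<int>& dj,
                             std::vector<int>& dk) {
  di.clear(); dj.clear(); dk.clear();
  if (connectivity == 6) {
    int a[6] = { 1, -1, 0, 0, 0, 0 };
    int b[6] = { 0, 0, 1, -1, 0, 0 };
    int c[6] = { 0, 0, 0, 0, 1, -1 };
    for (int t = 0; t < 6; ++t) { di.push_back(a[t]); dj.push_back(b[t]); dk.push_back(c[t]); }
  } else {
    for (int c = -1; c <= 1; ++c)
      for (int b = -1; b <= 1; ++b)
        for (int a = -1; a <= 1; ++a) {
          if (a == 0 && b == 0 && c == 0) continue;
          di.push_back(a); dj.push_back(b); dk.push_back(c);
        }
  }
}

// Connected-component labelling (BFS), 6- or 26-connectivity.
// Returns 1-based labels, 0 for background.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dim,
                                   int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int> di, dj, dk;
  neighbor_offsets(connectivity, nx, ny, di, dj, dk);
  int nneigh = (int)di.size();
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    lab[s] = next;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t cur = q.front(); q.pop();
      int i = (int)(cur % nx);
      int j = (int)((cur / nx) % ny);
      int k = (int)(cur / ((R_xlen_t)nx * ny));
      for (int t = 0; t < nneigh; ++t) {
        int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
        R_xlen_t nb = (R_xlen_t)ii + (R_xlen_t)jj * nx + (R_xlen_t)kk * nx * ny;
        if (mask[nb] && !lab[nb]) { lab[nb] = next; q.push(nb); }
      }
    }
  }
  return lab;
}

// Seeded region growing with the running-mean acceptance rule:
// a frontier voxel v is accepted iff HU(v) >= mean(region) + S.
// Frontier is processed best-first by HU, ties by linear index, so the first
// rejected voxel is the global frontier maximum and growth stops there.
// [[Rcpp::export]]
List cpp_region_grow(NumericVector hu, IntegerVector lung, IntegerVector dim,
                     IntegerVector seeds0, double S, int connectivity,
                     int max_voxels) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> in(n, 0), seen(n, 0);
  std::vector<int> di, dj, dk;
  neighbor_offsets(connectivity, nx, ny, di, dj, dk);
  int nneigh = (int)di.size();

  typedef std::pair<double, R_xlen_t> Node; // (-HU, index): max-HU first, then low index
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;

  double sum = 0.0;
  R_xlen_t count = 0;
  bool truncated = false;

  // seeds join unconditionally
  for (R_xlen_t s = 0; s < seeds0.size(); ++s) {
    R_xlen_t idx = seeds0[s];
    if (idx < 0 || idx >= n) stop("seed index out of bounds");
    if (in[idx]) continue;
    in[idx] = 1; seen[idx] = 1;
    sum += hu[idx]; ++count;
  }
  // frontier from seed neighbourhood
  for (R_xlen_t s = 0; s < seeds0.size(); ++s) {
    R_xlen_t idx = seeds0[s];
    int i = (int)(idx % nx);
    int j = (int)((idx / nx) % ny);
    int k = (int)(idx / ((R_xlen_t)nx * ny));
    for (int t = 0; t < nneigh; ++t) {
      int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
      R_xlen_t nb = (R_xlen_t)ii + (R_xlen_t)jj * nx + (R_xlen_t)kk * nx * ny;
      if (!seen[nb] && lung[nb]) { seen[nb] = 1; pq.push(Node(-hu[nb], nb)); }
    }
  }

  while (!pq.empty()) {
    if (count >= max_voxels) { truncated = true; break; }
    Node top = pq.top(); pq.pop();
    double v = -top.first;
    R_xlen_t idx = top.second;
    double mean = sum / (double)count;
    if (v < mean + S) break; // frontier maximum fails: nothing else can pass
    in[idx] = 1;
    sum += v; ++count;
    int i = (int)(idx % nx);
    int j = (int)((idx / nx) % ny);
    int k = (int)(idx / ((R_xlen_t)nx * ny));
    for (int t = 0; t < nneigh; ++t) {
      int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
      R_xlen_t nb = (R_xlen_t)ii + (R_xlen_t)jj * nx + (R_xlen_t)kk * nx * ny;
      if (!seen[nb] && lung[nb]) { seen[nb] = 1; pq.push(Node(-hu[nb], nb)); }
    }
  }

  IntegerVector out(n, 0);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = in[i] ? 1 : 0;
  return List::create(_["mask"] = out, _["truncated"] = truncated,
                      _["n_voxels"] = (double)count);
}

// Front-propagation arrival times from a source voxel over the mask, with a
// per-voxel speed field (Dijkstra on the 26-connected grid graph; edge cost =
// Euclidean step / harmonic mean speed).  Approximates fast marching with a
// centredness-weighted speed.
// [[Rcpp::export]]
NumericVector cpp_arrival_time(IntegerVector mask, IntegerVector dim,
                               NumericVector spacing, NumericVector speed,
                               int source0) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector T(n, INF);
  std::vector<int> di, dj, dk;
  neighbor_offsets(26, nx, ny, di, dj, dk);
  int nneigh = (int)di.size();
  std::vector<double> step(nneigh);
  for (int t = 0; t < nneigh; ++t) {
    double dx = di[t] * spacing[0], dy = dj[t] * spacing[1], dz = dk[t] * spacing[2];
    step[t] = std::sqrt(dx * dx + dy * dy + dz * dz);
  }

  typedef std::pair<double, R_xlen_t> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  if (source0 < 0 || source0 >= n || !mask[source0]) stop("source not in mask");
  T[source0] = 0.0;
  pq.push(Node(0.0, source0));
  while (!pq.empty()) {
    Node top = pq.top(); pq.pop();
    double t0 = top.first;
    R_xlen_t idx = top.second;
    if (t0 > T[idx]) continue;
    int i = (int)(idx % nx);
    int j = (int)((idx / nx) % ny);
    int k = (int)(idx / ((R_xlen_t)nx * ny));
    for (int t = 0; t < nneigh; ++t) {
      int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
      R_xlen_t nb = (R_xlen_t)ii + (R_xlen_t)jj * nx + (R_xlen_t)kk * nx * ny;
      if (!mask[nb]) continue;
      double sl = 0.5 * (1.0 / speed[idx] + 1.0 / speed[nb]);
      double alt = t0 + step[t] * sl;
      if (alt < T[nb]) { T[nb] = alt; pq.push(Node(alt, nb)); }
    }
  }
  return T;
}

// Steepest-descent backtrace on an arrival-time field from start0 until a
// voxel flagged in `stopmask` (the existing skeleton / source) is reached.
// Returns the 0-based linear indices of the path including both ends.
// [[Rcpp::export]]
IntegerVector cpp_backtrace(NumericVector T, IntegerVector dim, int start0,
                            IntegerVector stopmask) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<int> di, dj, dk;
  neighbor_offsets(26, nx, ny, di, dj, dk);
  int nneigh = (int)di.size();
  std::vector<int> path;
  R_xlen_t cur = start0;
  path.push_back((int)cur);
  R_xlen_t guard = (R_xlen_t)nx * ny * nz + 1;
  while (!stopmask[cur] && guard-- > 0) {
    int i = (int)(cur % nx);
    int j = (int)((cur / nx) % ny);
    int k = (int)(cur / ((R_xlen_t)nx * ny));
    double best = T[cur];
    double bestStop = INF;
    R_xlen_t bestIdx = -1, stopIdx = -1;
    for (int t = 0; t < nneigh; ++t) {
      int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
      R_xlen_t nb = (R_xlen_t)ii + (R_xlen_t)jj * nx + (R_xlen_t)kk * nx * ny;
      if (!R_finite(T[nb])) continue;
      if (stopmask[nb] && T[nb] < bestStop) { bestStop = T[nb]; stopIdx = nb; }
      if (T[nb] < best) { best = T[nb]; bestIdx = nb; }
    }
    // attach to the skeleton as soon as it is adjacent
    if (stopIdx >= 0) { path.push_back((int)stopIdx); break; }
    if (bestIdx < 0) break; // local minimum (should be the source)
    cur = bestIdx;
    path.push_back((int)cur);
  }
  return wrap(path);
}

// Mark all voxels within radius r_s (mm) of each given centre voxel.
// Used to record the territory covered by a growing skeleton.
// [[Rcpp::export]]
void cpp_stamp_balls(IntegerVector covered, IntegerVector dim,
                     NumericVector spacing, IntegerVector centres0,
                     NumericVector radii) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  for (R_xlen_t s = 0; s < centres0.size(); ++s) {
    R_xlen_t idx = centres0[s];
    double r = radii[s];
    int i = (int)(idx % nx);
    int j = (int)((idx / nx) % ny);
    int k = (int)(idx / ((R_xlen_t)nx * ny));
    int ri = (int)std::floor(r / spacing[0]);
    int rj = (int)std::floor(r / spacing[1]);
    int rk = (int)std::floor(r / spacing[2]);
    for (int kk = std::max(0, k - rk); kk <= std::min(nz - 1, k + rk); ++kk)
      for (int jj = std::max(0, j - rj); jj <= std::min(ny - 1, j + rj); ++jj)
        for (int ii = std::max(0, i - ri); ii <= std::min(nx - 1, i + ri); ++ii) {
          double dx = (ii - i) * spacing[0];
          double dy = (jj - j) * spacing[1];
          double dz = (kk - k) * spacing[2];
          if (dx * dx + dy * dy + dz * dz <= r * r) {
            covered[(R_xlen_t)ii + (R_xlen_t)jj * nx + (R_xlen_t)kk * nx * ny] = 1;
          }
        }
  }
}

// Rasterize a set of polyline segments into a voxel tube mask: a voxel is
// foreground iff its centre (origin + index*spacing) lies within `radius` mm
// of any segment (point-to-segment distance in world mm).
// Segments are given as two n x 3 matrices of endpoints (mm).
// [[Rcpp::export]]
IntegerVector cpp_rasterize_segments(NumericMatrix A, NumericMatrix B,
                                     IntegerVector dim, NumericVector spacing,
                                     NumericVector origin, double radius) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector out(n, 0);
  double r2 = radius * radius;
  for (int s = 0; s < A.nrow(); ++s) {
    double ax = A(s, 0), ay = A(s, 1), az = A(s, 2);
    double bx = B(s, 0), by = B(s, 1), bz = B(s, 2);
    double lox = std::min(ax, bx) - radius, hix = std::max(ax, bx) + radius;
    double loy = std::min(ay, by) - radius, hiy = std::max(ay, by) + radius;
    double loz = std::min(az, bz) - radius, hiz = std::max(az, bz) + radius;
    int i0 = std::max(0, (int)std::ceil((lox - origin[0]) / spacing[0]));
    int i1 = std::min(nx - 1, (int)std::floor((hix - origin[0]) / spacing[0]));
    int j0 = std::max(0, (int)std::ceil((loy - origin[1]) / spacing[1]));
    int j1 = std::min(ny - 1, (int)std::floor((hiy - origin[1]) / spacing[1]));
    int k0 = std::max(0, (int)std::ceil((loz - origin[2]) / spacing[2]));
    int k1 = std::min(nz - 1, (int)std::floor((hiz - origin[2]) / spacing[2]));
    double ux = bx - ax, uy = by - ay, uz = bz - az;
    double uu = ux * ux + uy * uy + uz * uz;
    for (int k = k0; k <= k1; ++k) {
      double pz = origin[2] + k * spacing[2];
      for (int j = j0; j <= j1; ++j) {
        double py = origin[1] + j * spacing[1];
        for (int i = i0; i <= i1; ++i) {
          R_xlen_t idx = (R_xlen_t)i + (R_xlen_t)j * nx + (R_xlen_t)k * nx * ny;
          if (out[idx]) continue;
          double px = origin[0] + i * spacing[0];
          double wx = px - ax, wy = py - ay, wz = pz - az;
          double t = uu > 0 ? (wx * ux + wy * uy + wz * uz) / uu : 0.0;
          if (t < 0 || t > 1) continue; // open cylinder: no end caps
          double dx = wx - t * ux, dy = wy - t * uy, dz = wz - t * uz;
          if (dx * dx + dy * dy + dz * dz <= r2) out[idx] = 1;
        }
      }
    }
  }
  return out;
}
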