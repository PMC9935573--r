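#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdlib>
using namespace Rcpp;

// Column-major 3D indexing throughout: idx = x + nx*(y + ny*z), 0-based.

// ---------------------------------------------------------------------------
// Squared Euclidean distance transform, separable lower-envelope algorithm,
// with per-axis physical spacing. Distances are to the nearest background
// voxel *center*; the volume border is not treated as background.
// ---------------------------------------------------------------------------

static const double BIG = 1e20;

static void dt1d(std::vector<double>& f, std::vector<double>& d, int n, double h) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; q++) {
    double s = 0.0;
    while (true) {
      int p = v[k];
      s = (f[q] - f[p] + (double)(q + p) * (q - p) * h * h) / (2.0 * h * (q - p));
      if (s <= z[k]) {
        k--;
      } else {
        break;
      }
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    double x = q * h;
    while (z[k + 1] < x) k++;
    double dx = x - v[k] * h;
    d[q] = dx * dx + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = mask[i] ? BIG : 0.0;

  std::vector<double> f, d;
  // x
  f.assign(nx, 0.0); d.assign(nx, 0.0);
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; i++) f[i] = out[base + i];
      dt1d(f, d, nx, spacing[0]);
      for (int i = 0; i < nx; i++) out[base + i] = d[i];
    }
  // y
  f.assign(ny, 0.0); d.assign(ny, 0.0);
  for (int k = 0; k < nz; k++)
    for (int i = 0; i < nx; i++) {
      for (int j = 0; j < ny; j++) f[j] = out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
      dt1d(f, d, ny, spacing[1]);
      for (int j = 0; j < ny; j++) out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = d[j];
    }
  // z
  f.assign(nz, 0.0); d.assign(nz, 0.0);
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++) {
      for (int k = 0; k < nz; k++) f[k] = out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
      dt1d(f, d, nz, spacing[2]);
      for (int k = 0; k < nz; k++) out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = d[k];
    }
  for (R_xlen_t i = 0; i < n; i++) if (out[i] >= BIG) out[i] = R_PosInf;
  return out;
}

// ---------------------------------------------------------------------------
// Connected-component labeling (6- or 26-connectivity).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim, int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; s++) {
    if (!mask[s] || lab[s]) continue;
    next++;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t c = stack.back(); stack.pop_back();
      int x = (int)(c % nx), y = (int)((c / nx) % ny), z = (int)(c / ((R_xlen_t)nx * ny));
      for (int dz = -1; dz <= 1; dz++)
        for (int dy = -1; dy <= 1; dy++)
          for (int dx = -1; dx <= 1; dx++) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            if (connectivity == 6 && std::abs(dx) + std::abs(dy) + std::abs(dz) != 1) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
            R_xlen_t q = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
            if (mask[q] && !lab[q]) { lab[q] = next; stack.push_back(q); }
          }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Topology-preserving sequential thinning. A voxel is deletable when it is a
// simple point (one 26-connected object component in the punctured 3x3x3
// neighborhood AND one 6-connected background component in the 18-neighborhood
// touching a face neighbor) and not a curve endpoint (<= 1 object neighbor).
// Deletion is sequential in increasing priority (distance-to-boundary), which
// keeps the retained curve centered on the medial axis.
// ---------------------------------------------------------------------------

static inline int off3(int dx, int dy, int dz) { return (dx + 1) + 3 * ((dy + 1) + 3 * (dz + 1)); }

static bool is_simple(const bool nb[27]) {
  // one 26-connected object component among the 26 neighbors
  int lbl[27] = {0};
  int ncomp = 0;
  int st[27], nst;
  for (int i = 0; i < 27; i++) {
    if (i == 13 || !nb[i] || lbl[i]) continue;
    ncomp++;
    if (ncomp > 1) return false;
    nst = 0; st[nst++] = i; lbl[i] = ncomp;
    while (nst > 0) {
      int c = st[--nst];
      int cx = c % 3, cy = (c / 3) % 3, cz = c / 9;
      for (int dz = -1; dz <= 1; dz++)
        for (int dy = -1; dy <= 1; dy++)
          for (int dx = -1; dx <= 1; dx++) {
            int x = cx + dx, y = cy + dy, z = cz + dz;
            if (x < 0 || x > 2 || y < 0 || y > 2 || z < 0 || z > 2) continue;
            int q = x + 3 * y + 9 * z;
            if (q == 13 || q == c) continue;
            if (nb[q] && !lbl[q]) { lbl[q] = ncomp; st[nst++] = q; }
          }
    }
  }
  if (ncomp != 1) return false;

  // one 6-connected background component in N18 seeded at face neighbors
  int blbl[27] = {0};
  int nbk = 0;
  static const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  for (int t0 = 0; t0 < 6; t0++) {
    int i = off3(d6[t0][0], d6[t0][1], d6[t0][2]);
    if (nb[i] || blbl[i]) continue;
    nbk++;
    if (nbk > 1) return false;
    nst = 0; st[nst++] = i; blbl[i] = nbk;
    while (nst > 0) {
      int c = st[--nst];
      int cx = c % 3, cy = (c / 3) % 3, cz = c / 9;
      for (int t = 0; t < 6; t++) {
        int x = cx + d6[t][0], y = cy + d6[t][1], z = cz + d6[t][2];
        if (x < 0 || x > 2 || y < 0 || y > 2 || z < 0 || z > 2) continue;
        int q = x + 3 * y + 9 * z;
        if (q == 13) continue;
        if (std::abs(x - 1) + std::abs(y - 1) + std::abs(z - 1) > 2) continue; // stay in N18
        if (!nb[q] && !blbl[q]) { blbl[q] = nbk; st[nst++] = q; }
      }
    }
  }
  return nbk == 1;
}

// [[Rcpp::export]]
LogicalVector cpp_thin(LogicalVector mask_, IntegerVector dim, NumericVector priority) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> m(n);
  for (R_xlen_t i = 0; i < n; i++) m[i] = mask_[i] ? 1 : 0;

  bool nb[27];
  static const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};

  auto getnb = [&](R_xlen_t idx, bool nbv[27]) {
    int x = (int)(idx % nx), y = (int)((idx / nx) % ny), z = (int)(idx / ((R_xlen_t)nx * ny));
    for (int dz = -1; dz <= 1; dz++)
      for (int dy = -1; dy <= 1; dy++)
        for (int dx = -1; dx <= 1; dx++) {
          int xx = x + dx, yy = y + dy, zz = z + dz;
          bool v = false;
          if (xx >= 0 && xx < nx && yy >= 0 && yy < ny && zz >= 0 && zz < nz)
            v = m[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)] != 0;
          nbv[off3(dx, dy, dz)] = v;
        }
  };
  auto count_obj = [&](const bool nbv[27]) {
    int c = 0;
    for (int i = 0; i < 27; i++) if (i != 13 && nbv[i]) c++;
    return c;
  };
  auto is_border = [&](const bool nbv[27]) {
    for (int t = 0; t < 6; t++) if (!nbv[off3(d6[t][0], d6[t][1], d6[t][2])]) return true;
    return false;
  };

  std::vector< std::pair<double, R_xlen_t> > cand;
  bool changed = true;
  while (changed) {
    changed = false;
    cand.clear();
    for (R_xlen_t i = 0; i < n; i++) {
      if (!m[i]) continue;
      getnb(i, nb);
      if (!is_border(nb)) continue;
      if (count_obj(nb) <= 1) continue;  // endpoint / isolated: keep
      if (is_simple(nb)) cand.push_back(std::make_pair(priority[i], i));
    }
    std::sort(cand.begin(), cand.end());
    for (size_t c = 0; c < cand.size(); c++) {
      R_xlen_t i = cand[c].second;
      if (!m[i]) continue;
      getnb(i, nb);
      if (count_obj(nb) <= 1) continue;
      if (!is_simple(nb)) continue;
      m[i] = 0;
      changed = true;
    }
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = m[i] != 0;
  return out;
}

// ---------------------------------------------------------------------------
// Marker-based watershed by priority flooding (6-connected growth from the
// markers in decreasing priority, e.g. the interior distance transform).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_watershed(LogicalVector mask, IntegerVector dim, NumericVector priority,
                            IntegerVector markers) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);
  typedef std::pair<double, R_xlen_t> P;
  std::priority_queue<P> pq;
  for (R_xlen_t i = 0; i < n; i++) {
    lab[i] = markers[i];
    if (markers[i] > 0) pq.push(std::make_pair(priority[i], i));
  }
  static const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  while (!pq.empty()) {
    P pr = pq.top(); pq.pop();
    R_xlen_t i = pr.second;
    int x = (int)(i % nx), y = (int)((i / nx) % ny), z = (int)(i / ((R_xlen_t)nx * ny));
    for (int t = 0; t < 6; t++) {
      int xx = x + d6[t][0], yy = y + d6[t][1], zz = z + d6[t][2];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
      R_xlen_t q = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
      if (!mask[q] || lab[q] > 0) continue;
      lab[q] = lab[i];
      pq.push(std::make_pair(priority[q], q));
    }
  }
  return lab;
}

// [[Rcpp::export]]
LogicalVector cpp_local_maxima(NumericVector v, IntegerVector dim, LogicalVector mask) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; i++) {
    if (!mask[i] || v[i] <= 0) { out[i] = false; continue; }
    int x = (int)(i % nx), y = (int)((i / nx) % ny), z = (int)(i / ((R_xlen_t)nx * ny));
    bool ok = true;
    for (int dz = -1; dz <= 1 && ok; dz++)
      for (int dy = -1; dy <= 1 && ok; dy++)
        for (int dx = -1; dx <= 1 && ok; dx++) {
          if (dx == 0 && dy == 0 && dz == 0) continue;
          int xx = x + dx, yy = y + dy, zz = z + dz;
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
          R_xlen_t q = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
          if (mask[q] && v[q] > v[i]) ok = false;
        }
    out[i] = ok;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Trilinear / nearest-neighbour resampling onto an isotropic grid. Input
// voxel i sits at physical position i*spacing along each axis (0-based);
// output voxel j at j*target.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector vol, IntegerVector dim_in, NumericVector spacing,
                           IntegerVector dim_out, double target, int order) {
  int nx = dim_in[0], ny = dim_in[1], nz = dim_in[2];
  int ox = dim_out[0], oy = dim_out[1], oz = dim_out[2];
  R_xlen_t n = (R_xlen_t)ox * oy * oz;
  NumericVector out(n);
  for (int k = 0; k < oz; k++) {
    double cz = k * target / spacing[2];
    if (cz < 0) cz = 0; if (cz > nz - 1) cz = nz - 1;
    for (int j = 0; j < oy; j++) {
      double cy = j * target / spacing[1];
      if (cy < 0) cy = 0; if (cy > ny - 1) cy = ny - 1;
      for (int i = 0; i < ox; i++) {
        double cx = i * target / spacing[0];
        if (cx < 0) cx = 0; if (cx > nx - 1) cx = nx - 1;
        double val;
        if (order == 0) {
          int x = (int)std::floor(cx + 0.5), y = (int)std::floor(cy + 0.5), z = (int)std::floor(cz + 0.5);
          val = vol[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)];
        } else {
          int x0 = (int)std::floor(cx), y0 = (int)std::floor(cy), z0 = (int)std::floor(cz);
          int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1), z1 = std::min(z0 + 1, nz - 1);
          double fx = cx - x0, fy = cy - y0, fz = cz - z0;
          double c000 = vol[x0 + (R_xlen_t)nx * (y0 + (R_xlen_t)ny * z0)];
          double c100 = vol[x1 + (R_xlen_t)nx * (y0 + (R_xlen_t)ny * z0)];
          double c010 = vol[x0 + (R_xlen_t)nx * (y1 + (R_xlen_t)ny * z0)];
          double c110 = vol[x1 + (R_xlen_t)nx * (y1 + (R_xlen_t)ny * z0)];
          double c001 = vol[x0 + (R_xlen_t)nx * (y0 + (R_xlen_t)ny * z1)];
          double c101 = vol[x1 + (R_xlen_t)nx * (y0 + (R_xlen_t)ny * z1)];
          double c011 = vol[x0 + (R_xlen_t)nx * (y1 + (R_xlen_t)ny * z1)];
          double c111 = vol[x1 + (R_xlen_t)nx * (y1 + (R_xlen_t)ny * z1)];
          double c00 = c000 * (1 - fx) + c100 * fx;
          double c10 = c010 * (1 - fx) + c110 * fx;
          double c01 = c001 * (1 - fx) + c101 * fx;
          double c11 = c011 * (1 - fx) + c111 * fx;
          double c0 = c00 * (1 - fy) + c10 * fy;
          double c1 = c01 * (1 - fy) + c11 * fy;
          val = c0 * (1 - fz) + c1 * fz;
        }
        out[i + (R_xlen_t)ox * (j + (R_xlen_t)oy * k)] = val;
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Tube rasterization against a densely resampled centerline polyline: a voxel
// belongs to the lumen iff its center lies within the radius attached to the
// nearest point of the polyline, with distance measured to the polyline
// *segments* (not just their endpoints) so the axial discretization of the
// curve introduces no boundary bias; the radius is interpolated linearly
// along each segment. Voxel center of index i (0-based) is at i*spacing
// (mm); pts are mm coordinates, radii mm.
// ---------------------------------------------------------------------------

// Returns the per-voxel signed margin min(dist_to_centerline - radius) in mm
// (negative inside the lumen), folded with `margin_in` so several arteries
// accumulate into one field. The caller derives the binary lumen
// (margin <= 0) and the partial-volume fraction from it.

// [[Rcpp::export]]
NumericVector cpp_rasterize_tube(NumericMatrix pts, NumericVector radii, NumericVector spacing,
                                 IntegerVector dim, double stamp_r, NumericVector margin_in) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> bestd2(n, 1e30), bestr(n, -1.0);
  int np = pts.nrow();
  for (int p = 0; p + 1 < np; p++) {
    double ax = pts(p, 0), ay = pts(p, 1), az = pts(p, 2);
    double bx = pts(p + 1, 0), by = pts(p + 1, 1), bz = pts(p + 1, 2);
    double ux = bx - ax, uy = by - ay, uz = bz - az;
    double uu = ux * ux + uy * uy + uz * uz;
    double lox = std::min(ax, bx), hix = std::max(ax, bx);
    double loy = std::min(ay, by), hiy = std::max(ay, by);
    double loz = std::min(az, bz), hiz = std::max(az, bz);
    int x0 = std::max(0, (int)std::ceil((lox - stamp_r) / spacing[0]));
    int x1 = std::min(nx - 1, (int)std::floor((hix + stamp_r) / spacing[0]));
    int y0 = std::max(0, (int)std::ceil((loy - stamp_r) / spacing[1]));
    int y1 = std::min(ny - 1, (int)std::floor((hiy + stamp_r) / spacing[1]));
    int z0 = std::max(0, (int)std::ceil((loz - stamp_r) / spacing[2]));
    int z1 = std::min(nz - 1, (int)std::floor((hiz + stamp_r) / spacing[2]));
    for (int z = z0; z <= z1; z++) {
      double vz = z * spacing[2] - az;
      for (int y = y0; y <= y1; y++) {
        double vy = y * spacing[1] - ay;
        for (int x = x0; x <= x1; x++) {
          double vx = x * spacing[0] - ax;
          double t = uu > 0 ? (vx * ux + vy * uy + vz * uz) / uu : 0.0;
          if (t < 0) t = 0; else if (t > 1) t = 1;
          double dx = vx - t * ux, dy = vy - t * uy, dz = vz - t * uz;
          double d2 = dx * dx + dy * dy + dz * dz;
          R_xlen_t q = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
          if (d2 < bestd2[q]) {
            bestd2[q] = d2;
            bestr[q] = (1 - t) * radii[p] + t * radii[p + 1];
          }
        }
      }
    }
  }
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) {
    double m = bestr[i] > 0 ? std::sqrt(bestd2[i]) - bestr[i] : 1e30;
    out[i] = std::min((double)margin_in[i], m);
  }
  return out;
}

// ---------------------------------------------------------------------------
// 4-connected 2D flood fill from a seed: the lumen cross-section is the
// connected in-plane region containing the centerline point.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
LogicalVector cpp_region_from_seed_2d(LogicalVector grid, IntegerVector dim2, int cx, int cy) {
  int nx = dim2[0], ny = dim2[1];
  LogicalVector out((R_xlen_t)nx * ny);
  if (cx < 0 || cx >= nx || cy < 0 || cy >= ny) return out;
  R_xlen_t s = cx + (R_xlen_t)nx * cy;
  if (!grid[s]) return out;
  std::vector<R_xlen_t> stack;
  stack.push_back(s);
  out[s] = true;
  static const int d4[4][2] = {{1,0},{-1,0},{0,1},{0,-1}};
  while (!stack.empty()) {
    R_xlen_t c = stack.back(); stack.pop_back();
    int x = (int)(c % nx), y = (int)(c / nx);
    for (int t = 0; t < 4; t++) {
      int xx = x + d4[t][0], yy = y + d4[t][1];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny) continue;
      R_xlen_t q = xx + (R_xlen_t)nx * yy;
      if (grid[q] && !out[q]) { out[q] = true; stack.push_back(q); }
    }
  }
  return out;
}
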