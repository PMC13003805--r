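#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
#include <algorithm>
using namespace Rcpp;

typedef R_xlen_t xlen;

static inline xlen vidx(int i, int j, int k, int nx, int ny) {
  return (xlen)i + nx * ((xlen)j + (xlen)ny * k);
}

// offsets of a digital ball of radius r (voxels), centre excluded optional
static std::vector<std::array<int, 3>> ball_offsets(double r) {
  std::vector<std::array<int, 3>> off;
  int ri = (int)std::floor(r);
  for (int dz = -ri; dz <= ri; ++dz)
    for (int dy = -ri; dy <= ri; ++dy)
      for (int dx = -ri; dx <= ri; ++dx)
        if (dx * dx + dy * dy + dz * dz <= r * r)
          off.push_back({dx, dy, dz});
  return off;
}

// Binary dilation with a spherical structuring element (outside = background).
// [[Rcpp::export]]
LogicalVector dilate_ball_cpp(LogicalVector mask, IntegerVector dim,
                              double radius_vox) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  auto off = ball_offsets(radius_vox);
  LogicalVector out((xlen)nx * ny * nz, false);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (!mask[vidx(i, j, k, nx, ny)]) continue;
        for (auto &o : off) {
          int x = i + o[0], y = j + o[1], z = k + o[2];
          if (x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz)
            out[vidx(x, y, z, nx, ny)] = true;
        }
      }
  out.attr("dim") = dim;
  return out;
}

// Binary erosion with a spherical structuring element.  Out-of-grid
// neighbours count as foreground, so that closing (dilation followed by this
// erosion) is extensive at the volume faces and never eats structures that
// touch the boundary.
// [[Rcpp::export]]
LogicalVector erode_ball_cpp(LogicalVector mask, IntegerVector dim,
                             double radius_vox) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  auto off = ball_offsets(radius_vox);
  LogicalVector out((xlen)nx * ny * nz, false);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (!mask[vidx(i, j, k, nx, ny)]) continue;
        bool keep = true;
        for (auto &o : off) {
          int x = i + o[0], y = j + o[1], z = k + o[2];
          if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz)
            continue; // outside = foreground
          if (!mask[vidx(x, y, z, nx, ny)]) {
            keep = false;
            break;
          }
        }
        if (keep) out[vidx(i, j, k, nx, ny)] = true;
      }
  out.attr("dim") = dim;
  return out;
}

// 26-connected component labelling (BFS); labels 1..n in scan order.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const xlen nvox = (xlen)nx * ny * nz;
  IntegerVector lab(nvox, 0);
  int next = 0;
  std::vector<xlen> stack;
  for (xlen s = 0; s < nvox; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      xlen v = stack.back();
      stack.pop_back();
      int i = v % nx, j = (v / nx) % ny, k = v / ((xlen)nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int x = i + dx, y = j + dy, z = k + dz;
            if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz)
              continue;
            xlen w = vidx(x, y, z, nx, ny);
            if (mask[w] && !lab[w]) {
              lab[w] = next;
              stack.push_back(w);
            }
          }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// ---- topology-preserving thinning ------------------------------------------

// Number of 26-connected foreground components in the 26-neighbourhood of the
// centre (centre excluded).
static int count_fg26(const int nb[27]) {
  int lab[27] = {0};
  int ncomp = 0;
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || lab[s]) continue;
    ++ncomp;
    std::vector<int> st{s};
    lab[s] = ncomp;
    while (!st.empty()) {
      int v = st.back();
      st.pop_back();
      int vi = v % 3, vj = (v / 3) % 3, vk = v / 9;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int x = vi + dx, y = vj + dy, z = vk + dz;
            if (x < 0 || x > 2 || y < 0 || y > 2 || z < 0 || z > 2) continue;
            int w = x + 3 * y + 9 * z;
            if (w == 13 || w == v || !nb[w] || lab[w]) continue;
            lab[w] = ncomp;
            st.push_back(w);
          }
    }
  }
  return ncomp;
}

// Number of 6-connected background components in the 18-neighbourhood that are
// 6-adjacent to the centre (Bertrand-Malandain background topological number).
static int count_bg6(const int nb[27]) {
  // 18-neighbourhood: offsets with |dx|+|dy|+|dz| <= 2, excluding centre
  bool in18[27], bg[27];
  for (int s = 0; s < 27; ++s) {
    int dx = s % 3 - 1, dy = (s / 3) % 3 - 1, dz = s / 9 - 1;
    int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
    in18[s] = (man >= 1 && man <= 2);
    bg[s] = in18[s] && !nb[s];
  }
  int lab[27] = {0};
  int ncomp = 0;
  static const int face[6] = {4, 10, 12, 14, 16, 22}; // 6-neighbours of centre
  for (int f = 0; f < 6; ++f) {
    int s = face[f];
    if (!bg[s] || lab[s]) continue;
    ++ncomp;
    std::vector<int> st{s};
    lab[s] = ncomp;
    while (!st.empty()) {
      int v = st.back();
      st.pop_back();
      int vi = v % 3, vj = (v / 3) % 3, vk = v / 9;
      static const int d6[6][3] = {{1, 0, 0},  {-1, 0, 0}, {0, 1, 0},
                                   {0, -1, 0}, {0, 0, 1},  {0, 0, -1}};
      for (int q = 0; q < 6; ++q) {
        int x = vi + d6[q][0], y = vj + d6[q][1], z = vk + d6[q][2];
        if (x < 0 || x > 2 || y < 0 || y > 2 || z < 0 || z > 2) continue;
        int w = x + 3 * y + 9 * z;
        if (!bg[w] || lab[w]) continue;
        lab[w] = ncomp;
        st.push_back(w);
      }
    }
  }
  return ncomp;
}

static inline void fill_neighbourhood(const std::vector<char> &fg, int i,
                                      int j, int k, int nx, int ny, int nz,
                                      int nb[27]) {
  int s = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++s) {
        int x = i + dx, y = j + dy, z = k + dz;
        nb[s] = (x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz)
                    ? fg[vidx(x, y, z, nx, ny)]
                    : 0;
      }
}

// Chamfer (3,4,5) distance transform to the background, used only to order
// voxel deletion so that thinning erodes inward and the skeleton stays medial.
static std::vector<int> chamfer_dt(const std::vector<char> &fg, int nx, int ny,
                                   int nz) {
  const xlen nvox = (xlen)nx * ny * nz;
  const int INF = 1 << 28;
  std::vector<int> d(nvox);
  for (xlen v = 0; v < nvox; ++v) d[v] = fg[v] ? INF : 0;
  auto w = [](int dx, int dy, int dz) {
    int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
    return m == 1 ? 3 : (m == 2 ? 4 : 5);
  };
  // forward pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        xlen v = vidx(i, j, k, nx, ny);
        if (!fg[v]) continue;
        int best = d[v];
        for (int dz = -1; dz <= 0; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dz == 0 && (dy > 0 || (dy == 0 && dx >= 0))) continue;
              int x = i + dx, y = j + dy, z = k + dz;
              int dn = (x >= 0 && x < nx && y >= 0 && y < ny && z >= 0)
                           ? d[vidx(x, y, z, nx, ny)]
                           : 0;
              best = std::min(best, dn + w(dx, dy, dz));
            }
        d[v] = best;
      }
  // backward pass
  for (int k = nz - 1; k >= 0; --k)
    for (int j = ny - 1; j >= 0; --j)
      for (int i = nx - 1; i >= 0; --i) {
        xlen v = vidx(i, j, k, nx, ny);
        if (!fg[v]) continue;
        int best = d[v];
        for (int dz = 0; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dz == 0 && (dy < 0 || (dy == 0 && dx <= 0))) continue;
              int x = i + dx, y = j + dy, z = k + dz;
              int dn = (x >= 0 && x < nx && y >= 0 && y < ny && z < nz)
                           ? d[vidx(x, y, z, nx, ny)]
                           : 0;
              best = std::min(best, dn + w(dx, dy, dz));
            }
        d[v] = best;
      }
  return d;
}

// Distance-ordered homotopic thinning to a curve skeleton.  A voxel is
// deleted only if it is simple (removal preserves both foreground and
// background topology: exactly one 26-connected foreground component in its
// 26-neighbourhood and one 6-connected background component in its
// 18-neighbourhood touching the centre) and not a curve endpoint (<= 1
// foreground 26-neighbour).
// [[Rcpp::export]]
LogicalVector skeletonize_cpp(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const xlen nvox = (xlen)nx * ny * nz;
  std::vector<char> fg(nvox);
  for (xlen v = 0; v < nvox; ++v) fg[v] = mask[v] ? 1 : 0;
  std::vector<int> dt = chamfer_dt(fg, nx, ny, nz);

  std::vector<xlen> cand;
  bool changed = true;
  int nb[27];
  while (changed) {
    changed = false;
    cand.clear();
    for (xlen v = 0; v < nvox; ++v) {
      if (!fg[v]) continue;
      int i = v % nx, j = (v / nx) % ny, k = v / ((xlen)nx * ny);
      // border voxel: some 6-neighbour is background (or outside)
      bool border = i == 0 || i == nx - 1 || j == 0 || j == ny - 1 || k == 0 ||
                    k == nz - 1;
      if (!border) {
        static const int d6[6][3] = {{1, 0, 0},  {-1, 0, 0}, {0, 1, 0},
                                     {0, -1, 0}, {0, 0, 1},  {0, 0, -1}};
        for (int q = 0; q < 6 && !border; ++q)
          border = !fg[vidx(i + d6[q][0], j + d6[q][1], k + d6[q][2], nx, ny)];
      }
      if (border) cand.push_back(v);
    }
    std::stable_sort(cand.begin(), cand.end(),
                     [&dt](xlen a, xlen b) { return dt[a] < dt[b]; });
    for (xlen v : cand) {
      if (!fg[v]) continue;
      int i = v % nx, j = (v / nx) % ny, k = v / ((xlen)nx * ny);
      fill_neighbourhood(fg, i, j, k, nx, ny, nz, nb);
      int nfg = 0;
      for (int s = 0; s < 27; ++s)
        if (s != 13 && nb[s]) ++nfg;
      if (nfg <= 1) continue; // endpoint or isolated: keep
      if (count_fg26(nb) != 1) continue;
      if (count_bg6(nb) != 1) continue;
      fg[v] = 0;
      changed = true;
    }
  }
  LogicalVector out(nvox);
  for (xlen v = 0; v < nvox; ++v) out[v] = fg[v] != 0;
  out.attr("dim") = dim;
  return out;
}

// ---- star-line radius ------------------------------------------------------

static inline double sample_field(const NumericVector &field, int nx, int ny,
                                  int nz, double x, double y, double z) {
  // trilinear interpolation; outside grid = background (0)
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  double fx = x - i0, fy = y - j0, fz = z - k0;
  double acc = 0.0;
  for (int dz = 0; dz <= 1; ++dz)
    for (int dy = 0; dy <= 1; ++dy)
      for (int dx = 0; dx <= 1; ++dx) {
        int i = i0 + dx, j = j0 + dy, k = k0 + dz;
        double val =
            (i >= 0 && i < nx && j >= 0 && j < ny && k >= 0 && k < nz)
                ? field[vidx(i, j, k, nx, ny)]
                : 0.0;
        acc += val * (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) *
               (dz ? fz : 1 - fz);
      }
  return acc;
}

static double ray_to_boundary(const NumericVector &field, int nx, int ny,
                              int nz, const double p[3], const double dir[3],
                              double step, double tmax) {
  double prev = sample_field(field, nx, ny, nz, p[0], p[1], p[2]);
  double tprev = 0.0;
  for (double t = step; t <= tmax; t += step) {
    double cur = sample_field(field, nx, ny, nz, p[0] + t * dir[0],
                              p[1] + t * dir[1], p[2] + t * dir[2]);
    if (cur < 0.5) {
      double frac = (prev - 0.5) / std::max(prev - cur, 1e-12);
      return tprev + frac * step;
    }
    prev = cur;
    tprev = t;
  }
  return tmax;
}

// Star-line radius at skeletal points: for each point cast symmetric ray
// pairs along the supplied directions, measure the chord length through the
// mask along each pair, and return half the minimum chord (in voxel units).
// points: n x 3 (0-based voxel coordinates); dirs: m x 3 unit vectors.
// [[Rcpp::export]]
NumericVector starline_radius_cpp(NumericVector field, IntegerVector dim,
                                  NumericMatrix points, NumericMatrix dirs,
                                  double step) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double tmax = std::sqrt((double)nx * nx + (double)ny * ny +
                                (double)nz * nz);
  const int npt = points.nrow(), ndir = dirs.nrow();
  NumericVector rad(npt);
  for (int q = 0; q < npt; ++q) {
    double p[3] = {points(q, 0), points(q, 1), points(q, 2)};
    // tempered minimum: average of the two shortest chords.  The plain
    // minimum over the digitized surface is biased low by ~0.1 voxel
    // (extreme-value statistics of the staircase); averaging the two
    // shortest chords removes most of that bias (validated against the
    // distance-transform oracle) while still rejecting oblique chords.
    double best1 = tmax, best2 = tmax;
    for (int m = 0; m < ndir; ++m) {
      double d[3] = {dirs(m, 0), dirs(m, 1), dirs(m, 2)};
      double nd[3] = {-d[0], -d[1], -d[2]};
      double tp = ray_to_boundary(field, nx, ny, nz, p, d, step, tmax);
      double tm = ray_to_boundary(field, nx, ny, nz, p, nd, step, tmax);
      double chord = tp + tm;
      if (chord < best1) { best2 = best1; best1 = chord; }
      else if (chord < best2) best2 = chord;
    }
    rad[q] = 0.5 * (ndir > 1 ? 0.5 * (best1 + best2) : best1);
  }
  return rad;
}

// Assign every foreground voxel to the branch label of its nearest skeletal
// point (Euclidean distance in voxel units; ties -> lower label).
// Returns an integer array: 0 background, otherwise branch label.
// [[Rcpp::export]]
IntegerVector assign_voxels_cpp(LogicalVector mask, IntegerVector dim,
                                NumericMatrix points, IntegerVector labels) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const xlen nvox = (xlen)nx * ny * nz;
  const int npt = points.nrow();
  IntegerVector out(nvox, 0);
  if (npt == 0) {
    out.attr("dim") = dim;
    return out;
  }
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        xlen v = vidx(i, j, k, nx, ny);
        if (!mask[v]) continue;
        double bestd = 1e30;
        int bestl = 0;
        for (int q = 0; q < npt; ++q) {
          double dx = i - points(q, 0), dy = j - points(q, 1),
                 dz = k - points(q, 2);
          double d2 = dx * dx + dy * dy + dz * dz;
          int l = labels[q];
          if (d2 < bestd - 1e-12 ||
              (std::abs(d2 - bestd) <= 1e-12 && l < bestl)) {
            bestd = d2;
            bestl = l;
          }
        }
        out[v] = bestl;
      }
  out.attr("dim") = dim;
  return out;
}

// Per-voxel count of foreground 26-neighbours (for skeleton branch analysis).
// [[Rcpp::export]]
IntegerVector neighbour_count_cpp(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const xlen nvox = (xlen)nx * ny * nz;
  IntegerVector out(nvox, 0);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        xlen v = vidx(i, j, k, nx, ny);
        if (!mask[v]) continue;
        int c = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int x = i + dx, y = j + dy, z = k + dz;
              if (x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz &&
                  mask[vidx(x, y, z, nx, ny)])
                ++c;
            }
        out[v] = c;
      }
  out.attr("dim") = dim;
  return out;
}
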