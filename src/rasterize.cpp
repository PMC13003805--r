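#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Distance from point p to segment (a,b); returns squared distance.
static inline double seg_dist2(const double p[3], const double a[3],
                               const double b[3]) {
  double ab[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double ap[3] = {p[0] - a[0], p[1] - a[1], p[2] - a[2]};
  double denom = ab[0] * ab[0] + ab[1] * ab[1] + ab[2] * ab[2];
  double t = 0.0;
  if (denom > 0.0) {
    t = (ap[0] * ab[0] + ap[1] * ab[1] + ap[2] * ab[2]) / denom;
    t = std::max(0.0, std::min(1.0, t));
  }
  double d2 = 0.0;
  for (int k = 0; k < 3; ++k) {
    double d = p[k] - (a[k] + t * ab[k]);
    d2 += d * d;
  }
  return d2;
}

// Rasterize a set of straight tubes onto a voxel grid.
//
// A voxel belongs to a tube iff its centre lies within the tube radius of the
// tube axis (centre-in test).  Overlapping voxels are owned by the tube with
// the larger radius; ties go to the lower tube index.  Physical coordinates
// are voxel-centre based: position (um) = 0-based index * voxel_size.
//
// tubes: n x 7 matrix, columns x0 y0 z0 x1 y1 z1 radius, all in um.
// Returns list(mask = logical array, owner = integer array (0 = background),
//              tube_voxels = per-tube owned voxel counts,
//              axis_dist = distance (um) from voxel centre to owner axis).
// [[Rcpp::export]]
List rasterize_tubes_cpp(IntegerVector dim, double voxel_size,
                         NumericMatrix tubes) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  LogicalVector mask(nvox, false);
  IntegerVector owner(nvox, 0);
  NumericVector adist(nvox, NA_REAL);
  const int ntube = tubes.nrow();
  NumericVector tube_voxels(ntube, 0.0);

  for (int t = 0; t < ntube; ++t) {
    double a[3] = {tubes(t, 0), tubes(t, 1), tubes(t, 2)};
    double b[3] = {tubes(t, 3), tubes(t, 4), tubes(t, 5)};
    double r = tubes(t, 6);
    double r2 = r * r;
    // bounding box in voxel indices
    int lo[3], hi[3];
    for (int k = 0; k < 3; ++k) {
      double mn = std::min(a[k], b[k]) - r, mx = std::max(a[k], b[k]) + r;
      lo[k] = std::max(0, (int)std::floor(mn / voxel_size));
      int dmax = (k == 0 ? nx : (k == 1 ? ny : nz)) - 1;
      hi[k] = std::min(dmax, (int)std::ceil(mx / voxel_size));
    }
    for (int k = lo[2]; k <= hi[2]; ++k)
      for (int j = lo[1]; j <= hi[1]; ++j)
        for (int i = lo[0]; i <= hi[0]; ++i) {
          double p[3] = {i * voxel_size, j * voxel_size, k * voxel_size};
          double d2 = seg_dist2(p, a, b);
          if (d2 <= r2) {
            R_xlen_t idx = (R_xlen_t)i + nx * ((R_xlen_t)j + (R_xlen_t)ny * k);
            mask[idx] = true;
            int cur = owner[idx];
            bool take = (cur == 0);
            if (!take) {
              double rc = tubes(cur - 1, 6);
              take = (r > rc); // larger radius wins; tie keeps lower index
            }
            if (take) {
              owner[idx] = t + 1;
              adist[idx] = std::sqrt(d2);
            }
          }
        }
  }
  for (R_xlen_t v = 0; v < nvox; ++v)
    if (owner[v] > 0) tube_voxels[owner[v] - 1] += 1.0;
  mask.attr("dim") = dim;
  owner.attr("dim") = dim;
  adist.attr("dim") = dim;
  return List::create(_["mask"] = mask, _["owner"] = owner,
                      _["tube_voxels"] = tube_voxels,
                      _["axis_dist"] = adist);
}

// Block-average a 3D numeric array by an integer factor along every axis
// (partial-volume downsampling of a binary mask to a coarser grid).
// [[Rcpp::export]]
NumericVector downsample_mean_cpp(NumericVector vol, IntegerVector dim,
                                  int factor) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int mx = nx / factor, my = ny / factor, mz = nz / factor;
  NumericVector out((R_xlen_t)mx * my * mz, 0.0);
  const double w = 1.0 / (factor * factor * factor);
  for (int k = 0; k < mz * factor; ++k)
    for (int j = 0; j < my * factor; ++j)
      for (int i = 0; i < mx * factor; ++i) {
        R_xlen_t src = (R_xlen_t)i + nx * ((R_xlen_t)j + (R_xlen_t)ny * k);
        R_xlen_t dst = (R_xlen_t)(i / factor) +
                       mx * ((R_xlen_t)(j / factor) +
                             (R_xlen_t)my * (k / factor));
        out[dst] += vol[src] * w;
      }
  out.attr("dim") = IntegerVector::create(mx, my, mz);
  return out;
}
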