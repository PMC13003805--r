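#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Explicit finite-difference Bloch-Torrey evolution on a periodic grid.
//
// The transverse magnetization m = m_x + i m_y starts from `m0` (typically 1
// everywhere, or 0 inside vessels when intravascular spins are excluded) and
// is advanced with operator splitting: a 7-point-Laplacian diffusion step
// followed by exact local phase accrual exp(-i gamma dB dt).  At step
// `refocus_step` the magnetization is conjugated (ideal 180 degree pulse).
// The signal is |sum(m)| / sum(m0) recorded after each step listed in
// `echo_steps` (1-based step counts).  Intrinsic T1/T2 decay is excluded; it
// cancels in the pre/post-contrast signal ratio.
//
// dB: field offset in Tesla per voxel; gamma in rad s^-1 T^-1; D in m^2/s;
// h (voxel size) in m; dt in s.  Stability (D dt / h^2 <= 1/6) is enforced
// by the caller.
// `probe` (0-based voxel index, or -1) additionally records the local
// magnetization magnitude |m(probe)| at each echo, which for a linear field
// follows the free-diffusion attenuation exp(-gamma^2 G^2 D t^3 / 3)
// independently of the ensemble ramp dephasing.
// [[Rcpp::export]]
List bt_evolve_cpp(NumericVector dB, IntegerVector dim,
                   NumericVector m0, double gamma, double D,
                   double h, double dt, int n_steps,
                   IntegerVector echo_steps, int refocus_step,
                   int probe = -1) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const double kdiff = D * dt / (h * h);

  std::vector<double> re(nvox), im(nvox, 0.0), re2(nvox), im2(nvox);
  std::vector<double> pc(nvox), ps(nvox);
  double norm = 0.0;
  for (R_xlen_t v = 0; v < nvox; ++v) {
    re[v] = m0[v];
    norm += m0[v];
    double phi = -gamma * dB[v] * dt;
    pc[v] = std::cos(phi);
    ps[v] = std::sin(phi);
  }
  if (norm <= 0.0) stop("no initialized spins");

  // periodic neighbour index tables
  std::vector<int> xp(nx), xm(nx), yp(ny), ym(ny), zp(nz), zm(nz);
  for (int i = 0; i < nx; ++i) { xp[i] = (i + 1) % nx; xm[i] = (i + nx - 1) % nx; }
  for (int j = 0; j < ny; ++j) { yp[j] = (j + 1) % ny; ym[j] = (j + ny - 1) % ny; }
  for (int k = 0; k < nz; ++k) { zp[k] = (k + 1) % nz; zm[k] = (k + nz - 1) % nz; }

  NumericVector sig(echo_steps.size());
  NumericVector probe_mag(probe >= 0 ? echo_steps.size() : 0);
  int eidx = 0;
  const R_xlen_t sxy = (R_xlen_t)nx * ny;
  for (int step = 1; step <= n_steps; ++step) {
    for (int k = 0; k < nz; ++k) {
      R_xlen_t zo = sxy * k, zpo = sxy * zp[k], zmo = sxy * zm[k];
      for (int j = 0; j < ny; ++j) {
        R_xlen_t yo = (R_xlen_t)nx * j, ypo = (R_xlen_t)nx * yp[j],
                 ymo = (R_xlen_t)nx * ym[j];
        const double *rc = &re[zo + yo], *ic = &im[zo + yo];
        const double *ryp = &re[zo + ypo], *iyp = &im[zo + ypo];
        const double *rym = &re[zo + ymo], *iym = &im[zo + ymo];
        const double *rzp = &re[zpo + yo], *izp = &im[zpo + yo];
        const double *rzm = &re[zmo + yo], *izm = &im[zmo + yo];
        const double *cc = &pc[zo + yo], *cs = &ps[zo + yo];
        double *ro = &re2[zo + yo], *io = &im2[zo + yo];
        // contiguous interior (x neighbours are direct); wrap edges after
        for (int i = 1; i < nx - 1; ++i) {
          double lr = rc[i - 1] + rc[i + 1] + ryp[i] + rym[i] + rzp[i] +
                      rzm[i] - 6.0 * rc[i];
          double li = ic[i - 1] + ic[i + 1] + iyp[i] + iym[i] + izp[i] +
                      izm[i] - 6.0 * ic[i];
          double tr = rc[i] + kdiff * lr;
          double ti = ic[i] + kdiff * li;
          ro[i] = cc[i] * tr - cs[i] * ti;
          io[i] = cs[i] * tr + cc[i] * ti;
        }
        for (int e = 0; e < 2; ++e) {
          int i = e ? nx - 1 : 0;
          double lr = rc[xm[i]] + rc[xp[i]] + ryp[i] + rym[i] + rzp[i] +
                      rzm[i] - 6.0 * rc[i];
          double li = ic[xm[i]] + ic[xp[i]] + iyp[i] + iym[i] + izp[i] +
                      izm[i] - 6.0 * ic[i];
          double tr = rc[i] + kdiff * lr;
          double ti = ic[i] + kdiff * li;
          ro[i] = cc[i] * tr - cs[i] * ti;
          io[i] = cs[i] * tr + cc[i] * ti;
        }
      }
    }
    re.swap(re2);
    im.swap(im2);
    if (step == refocus_step)
      for (R_xlen_t v = 0; v < nvox; ++v) im[v] = -im[v];
    if (eidx < echo_steps.size() && step == echo_steps[eidx]) {
      double sr = 0.0, si = 0.0;
      for (R_xlen_t v = 0; v < nvox; ++v) { sr += re[v]; si += im[v]; }
      sig[eidx] = std::sqrt(sr * sr + si * si) / norm;
      if (probe >= 0)
        probe_mag[eidx] = std::sqrt(re[probe] * re[probe] +
                                    im[probe] * im[probe]);
      ++eidx;
    }
  }
  return List::create(_["signal"] = sig, _["probe"] = probe_mag);
}
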