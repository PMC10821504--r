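#ifndef MOLDFT_EVAL_BASIS_H
#define MOLDFT_EVAL_BASIS_H

#include "qc_common.h"

// Evaluate contracted Cartesian Gaussian shells at a batch of points.
// order = 0: values only; 1: + first derivatives; 2: + second derivs.
// Matrices are (npts x nbf_active) where the active basis functions are
// the concatenated components of the shells in `act` (indices into sh).
// colmap gives the global basis index of each active column.
struct BasisBatch {
  arma::mat phi;
  arma::mat dphi[3];
  arma::mat d2phi[6];  // xx, xy, xz, yy, yz, zz
  std::vector<arma::uword> colmap;
};

inline void eval_basis_batch(const std::vector<Shell>& sh,
                             const std::vector<int>& act,
                             const arma::mat& pts, int order,
                             BasisBatch& out) {
  int np = pts.n_rows;
  int ncol = 0;
  out.colmap.clear();
  for (int s : act) {
    for (int c = 0; c < ncart(sh[s].l); ++c)
      out.colmap.push_back(sh[s].offset + c);
    ncol += ncart(sh[s].l);
  }
  out.phi.zeros(np, ncol);
  if (order >= 1)
    for (int d = 0; d < 3; ++d) out.dphi[d].zeros(np, ncol);
  if (order >= 2)
    for (int d = 0; d < 6; ++d) out.d2phi[d].zeros(np, ncol);
  std::vector<std::array<int,3>> comps;
  int col0 = 0;
  for (int s : act) {
    const Shell& shl = sh[s];
    cart_components(shl.l, comps);
    int nc = comps.size();
    int npr = shl.alpha.size();
    for (int ip = 0; ip < np; ++ip) {
      double dx = pts(ip, 0) - shl.R[0];
      double dy = pts(ip, 1) - shl.R[1];
      double dz = pts(ip, 2) - shl.R[2];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 > shl.rcut2) continue;
      double f0 = 0.0, f1 = 0.0, f2 = 0.0;
      for (int k = 0; k < npr; ++k) {
        double e = shl.coef[k] * std::exp(-shl.alpha[k] * r2);
        f0 += e;
        f1 += shl.alpha[k] * e;
        f2 += shl.alpha[k] * shl.alpha[k] * e;
      }
      // power tables up to l+2
      double px[7], py[7], pz[7];
      px[0] = py[0] = pz[0] = 1.0;
      for (int t = 1; t <= shl.l + 2; ++t) {
        px[t] = px[t-1] * dx; py[t] = py[t-1] * dy; pz[t] = pz[t-1] * dz;
      }
      for (int c = 0; c < nc; ++c) {
        int i = comps[c][0], j = comps[c][1], k = comps[c][2];
        double sc = shl.scale[c];
        double P = px[i] * py[j] * pz[k];
        out.phi(ip, col0 + c) = sc * P * f0;
        if (order >= 1) {
          double gx = (i > 0 ? i * px[i-1] * py[j] * pz[k] * f0 : 0.0)
                      - 2.0 * px[i+1] * py[j] * pz[k] * f1;
          double gy = (j > 0 ? j * px[i] * py[j-1] * pz[k] * f0 : 0.0)
                      - 2.0 * px[i] * py[j+1] * pz[k] * f1;
          double gz = (k > 0 ? k * px[i] * py[j] * pz[k-1] * f0 : 0.0)
                      - 2.0 * px[i] * py[j] * pz[k+1] * f1;
          out.dphi[0](ip, col0 + c) = sc * gx;
          out.dphi[1](ip, col0 + c) = sc * gy;
          out.dphi[2](ip, col0 + c) = sc * gz;
        }
        if (order >= 2) {
          double hxx = (i > 1 ? i*(i-1)*px[i-2]*py[j]*pz[k]*f0 : 0.0)
                       - 2.0*(2*i+1)*px[i]*py[j]*pz[k]*f1
                       + 4.0*px[i+2]*py[j]*pz[k]*f2;
          double hyy = (j > 1 ? j*(j-1)*px[i]*py[j-2]*pz[k]*f0 : 0.0)
                       - 2.0*(2*j+1)*px[i]*py[j]*pz[k]*f1
                       + 4.0*px[i]*py[j+2]*pz[k]*f2;
          double hzz = (k > 1 ? k*(k-1)*px[i]*py[j]*pz[k-2]*f0 : 0.0)
                       - 2.0*(2*k+1)*px[i]*py[j]*pz[k]*f1
                       + 4.0*px[i]*py[j]*pz[k+2]*f2;
          double hxy = (i>0 && j>0 ? i*j*px[i-1]*py[j-1]*pz[k]*f0 : 0.0)
                       - 2.0*f1*((i>0 ? i*px[i-1]*py[j+1]*pz[k] : 0.0)
                               + (j>0 ? j*px[i+1]*py[j-1]*pz[k] : 0.0))
                       + 4.0*px[i+1]*py[j+1]*pz[k]*f2;
          double hxz = (i>0 && k>0 ? i*k*px[i-1]*py[j]*pz[k-1]*f0 : 0.0)
                       - 2.0*f1*((i>0 ? i*px[i-1]*py[j]*pz[k+1] : 0.0)
                               + (k>0 ? k*px[i+1]*py[j]*pz[k-1] : 0.0))
                       + 4.0*px[i+1]*py[j]*pz[k+1]*f2;
          double hyz = (j>0 && k>0 ? j*k*px[i]*py[j-1]*pz[k-1]*f0 : 0.0)
                       - 2.0*f1*((j>0 ? j*px[i]*py[j-1]*pz[k+1] : 0.0)
                               + (k>0 ? k*px[i]*py[j+1]*pz[k-1] : 0.0))
                       + 4.0*px[i]*py[j+1]*pz[k+1]*f2;
          out.d2phi[0](ip, col0 + c) = sc * hxx;
          out.d2phi[1](ip, col0 + c) = sc * hxy;
          out.d2phi[2](ip, col0 + c) = sc * hxz;
          out.d2phi[3](ip, col0 + c) = sc * hyy;
          out.d2phi[4](ip, col0 + c) = sc * hyz;
          out.d2phi[5](ip, col0 + c) = sc * hzz;
        }
      }
    }
    col0 += nc;
  }
}

// shells whose cutoff sphere intersects the bounding box of the points
inline std::vector<int> active_shells(const std::vector<Shell>& sh,
                                      const arma::mat& pts) {
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) {
    lo[d] = pts.col(d).min();
    hi[d] = pts.col(d).max();
  }
  std::vector<int> act;
  for (size_t s = 0; s < sh.size(); ++s) {
    double d2 = 0.0;
    for (int d = 0; d < 3; ++d) {
      double c = sh[s].R[d];
      if (c < lo[d]) d2 += (lo[d] - c) * (lo[d] - c);
      else if (c > hi[d]) d2 += (c - hi[d]) * (c - hi[d]);
    }
    if (d2 <= sh[s].rcut2) act.push_back(s);
  }
  return act;
}

#endif
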