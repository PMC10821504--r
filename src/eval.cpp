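// [[Rcpp::depends(RcppArmadillo)]]
#include "qc_common.h"
#include "eval_basis.h"

using namespace Rcpp;

// Pointwise density-derived quantities from per-spin density matrices.
// Returns rho (total), and optionally grad2 = |grad rho|^2,
// tau = 1/2 sum_i f_i |grad psi_i|^2 (from D), spin = rho_a - rho_b,
// lambda2 = middle eigenvalue of the density Hessian.
// [[Rcpp::export(name = ".cpp_field_eval")]]
List field_eval(List basis, arma::mat Da, arma::mat Db, arma::mat pts,
                bool want_grad2, bool want_tau, bool want_spin,
                bool want_lambda2) {
  std::vector<Shell> sh = shells_from_R(basis);
  int np = pts.n_rows;
  arma::vec rho(np, arma::fill::zeros), grad2, tau, spin, lam2;
  if (want_grad2) grad2.zeros(np);
  if (want_tau) tau.zeros(np);
  if (want_spin) spin.zeros(np);
  if (want_lambda2) lam2.zeros(np);
  arma::mat Dt = Da + Db;
  const int BS = 1024;
  BasisBatch bb;
  int order = want_lambda2 ? 2 : 1;
  for (int p0 = 0; p0 < np; p0 += BS) {
    int p1 = std::min(np, p0 + BS);
    arma::mat bpts = pts.rows(p0, p1 - 1);
    std::vector<int> act = active_shells(sh, bpts);
    if (act.empty()) continue;
    eval_basis_batch(sh, act, bpts, order, bb);
    int nc = bb.colmap.size();
    arma::uvec cols(bb.colmap.data(), nc, false);
    arma::mat Dts = Dt.submat(cols, cols);
    arma::mat zt = bb.phi * Dts;
    int nb = p1 - p0;
    arma::mat zs;
    if (want_spin || want_tau) {
      // spin density needs Da - Db; tau needs Dt
      if (want_spin) {
        arma::mat Dsp = Da - Db;
        arma::mat Dss = Dsp.submat(cols, cols);
        zs = bb.phi * Dss;
      }
    }
    rho.subvec(p0, p1 - 1) = arma::sum(zt % bb.phi, 1);
    if (want_spin)
      spin.subvec(p0, p1 - 1) = arma::sum(zs % bb.phi, 1);
    if (want_grad2 || want_lambda2) {
      arma::mat g(nb, 3);
      for (int d = 0; d < 3; ++d) {
        g.col(d) = 2.0 * arma::sum(zt % bb.dphi[d], 1);
        if (want_tau) {
          arma::mat zd = bb.dphi[d] * Dts;
          tau.subvec(p0, p1 - 1) += 0.5 * arma::sum(zd % bb.dphi[d], 1);
        }
      }
      if (want_grad2)
        grad2.subvec(p0, p1 - 1) = arma::sum(g % g, 1);
      if (want_lambda2) {
        // Hessian of rho: H_de = 2 sum_mn D (d2phi phi + dphi dphi)
        arma::mat zd[3];
        for (int d = 0; d < 3; ++d) zd[d] = bb.dphi[d] * Dts;
        static const int pairs[6][2] = {{0,0},{0,1},{0,2},{1,1},{1,2},{2,2}};
        for (int i = 0; i < nb; ++i) {
          double H[6];
          for (int q = 0; q < 6; ++q) {
            int d = pairs[q][0], e = pairs[q][1];
            H[q] = 2.0 * (arma::dot(zt.row(i), bb.d2phi[q].row(i)) +
                          arma::dot(zd[d].row(i), bb.dphi[e].row(i)));
          }
          // middle eigenvalue of the symmetric 3x3 in closed form
          // (trigonometric solution of the characteristic cubic)
          double a = H[0], b = H[3], c = H[5];
          double d12 = H[1], d13 = H[2], d23 = H[4];
          double q = (a + b + c) / 3.0;
          double aa = a - q, bbq = b - q, cq = c - q;
          double p2 = (aa*aa + bbq*bbq + cq*cq +
                       2.0 * (d12*d12 + d13*d13 + d23*d23)) / 6.0;
          double p = std::sqrt(std::max(p2, 0.0));
          if (p < 1e-30) {
            lam2(p0 + i) = q;
          } else {
            // det of (H - q I)/p
            double m11 = aa/p, m22 = bbq/p, m33 = cq/p;
            double m12 = d12/p, m13 = d13/p, m23 = d23/p;
            double detB = m11*(m22*m33 - m23*m23) - m12*(m12*m33 - m23*m13)
                        + m13*(m12*m23 - m22*m13);
            double r = detB / 2.0;
            r = std::min(1.0, std::max(-1.0, r));
            double phi = std::acos(r) / 3.0;
            double e1 = q + 2.0*p*std::cos(phi);
            double e3 = q + 2.0*p*std::cos(phi + 2.0*M_PI/3.0);
            lam2(p0 + i) = 3.0*q - e1 - e3;  // middle by trace
          }
        }
      }
    } else if (want_tau) {
      for (int d = 0; d < 3; ++d) {
        arma::mat zd = bb.dphi[d] * Dts;
        tau.subvec(p0, p1 - 1) += 0.5 * arma::sum(zd % bb.dphi[d], 1);
      }
    }
  }
  List out = List::create(_["rho"] = rho);
  if (want_grad2) out["grad2"] = grad2;
  if (want_tau) out["tau"] = tau;
  if (want_spin) out["spin"] = spin;
  if (want_lambda2) out["lambda2"] = lam2;
  return out;
}

// Steepest-ascent (near-grid watershed) assignment of grid voxels to
// local maxima of `val` (e.g. the ELF).  26-neighbour connectivity.
// Voxels with rho < rho_min stay unassigned (label 0).  Returns 1-based
// labels pointing at the attractor's linear voxel index.
// [[Rcpp::export(name = ".cpp_watershed")]]
IntegerVector watershed(NumericVector val, NumericVector rho,
                        IntegerVector dims, double rho_min) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<int> nxt(n);
  const double* v = val.begin();
  const double* r = rho.begin();
  // linear index: ix + nx*(iy + ny*iz)  (R array order)
  for (size_t i = 0; i < n; ++i) {
    if (r[i] < rho_min) { nxt[i] = -1; continue; }
    int ix = i % nx, iy = (i / nx) % ny, iz = i / ((size_t)nx * ny);
    double best = v[i];
    long besti = (long)i;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          int jx = ix + dx, jy = iy + dy, jz = iz + dz;
          if (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 || jz >= nz)
            continue;
          size_t j = jx + (size_t)nx * (jy + (size_t)ny * jz);
          if (v[j] > best || (v[j] == best && (long)j > besti)) {
            best = v[j];
            besti = (long)j;
          }
        }
    nxt[i] = (int)besti;
  }
  IntegerVector lab(n);
  std::vector<int> path;
  for (size_t i = 0; i < n; ++i) {
    if (nxt[i] < 0) { lab[i] = 0; continue; }
    if (lab[i] != 0) continue;
    path.clear();
    int cur = i;
    while (true) {
      if (lab[cur] > 0) break;               // known root downstream
      if (lab[cur] == -1) {                  // plateau cycle -> make it a max
        lab[cur] = cur + 1;
        break;
      }
      if (nxt[cur] == cur || nxt[cur] < 0) { // local max (or edge of data)
        lab[cur] = cur + 1;
        break;
      }
      path.push_back(cur);
      lab[cur] = -1;  // mark in-progress
      cur = nxt[cur];
    }
    int root = lab[cur];
    for (int p : path) lab[p] = root;
  }
  return lab;
}

// Yu-Trinkle fractional basin weights for population integration.
// Voxels are processed in descending field order; each voxel's basin
// weights are flux-weighted averages of its higher 6-neighbours'
// weights.  Populations are accumulated as sum rho * w * dV.
// vlab: final (merged) basin label per voxel (0 = unassigned); used
// for the attractor voxels and as the fallback.  Returns per-basin
// populations (length nb).
// [[Rcpp::export(name = ".cpp_yt_populations")]]
NumericVector yt_populations(NumericVector val, NumericVector rho,
                             IntegerVector dims, IntegerVector vlab,
                             int nb, double dV) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  const double* v = val.begin();
  const double* r = rho.begin();
  const int* lab = vlab.begin();
  // sort active voxels by descending field value (ties: higher index
  // first, matching the watershed tie-break)
  std::vector<int> order;
  order.reserve(n / 4);
  for (size_t i = 0; i < n; ++i)
    if (lab[i] > 0) order.push_back((int)i);
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    if (v[a] != v[b]) return v[a] > v[b];
    return a > b;
  });
  const int K = 4;  // weight slots per voxel
  std::vector<int> wb((size_t)n * K, 0);
  std::vector<float> ww((size_t)n * K, 0.0f);
  NumericVector pop(nb);
  int off[6];
  off[0] = 1; off[1] = -1; off[2] = nx; off[3] = -nx;
  off[4] = nx * ny; off[5] = -nx * ny;
  for (int i : order) {
    int ix = i % nx, iy = (i / nx) % ny, iz = i / (nx * ny);
    // collect flux to higher neighbours
    double flux[6];
    int nbr[6];
    double tot = 0.0;
    int nf = 0;
    for (int d = 0; d < 6; ++d) {
      int jx = ix, jy = iy, jz = iz;
      if (d == 0) ++jx; else if (d == 1) --jx;
      else if (d == 2) ++jy; else if (d == 3) --jy;
      else if (d == 4) ++jz; else --jz;
      if (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 || jz >= nz)
        continue;
      int j = i + off[d];
      if (lab[j] <= 0) continue;
      bool higher = (v[j] > v[i]) || (v[j] == v[i] && j > i);
      if (!higher) continue;
      double f = v[j] - v[i];
      if (f <= 0) f = 1e-30;  // plateau: equal share
      flux[nf] = f; nbr[nf] = j; ++nf;
      tot += f;
    }
    float* wi = ww.data() + (size_t)i * K;
    int* bi = wb.data() + (size_t)i * K;
    if (nf == 0) {
      bi[0] = lab[i];
      wi[0] = 1.0f;
    } else {
      // accumulate neighbour weights
      for (int q = 0; q < nf; ++q) {
        double share = flux[q] / tot;
        const float* wj = ww.data() + (size_t)nbr[q] * K;
        const int* bj = wb.data() + (size_t)nbr[q] * K;
        for (int s = 0; s < K; ++s) {
          if (bj[s] == 0) break;
          double add = share * wj[s];
          // insert into this voxel's slots
          int t = 0;
          for (; t < K; ++t) {
            if (bi[t] == bj[s]) { wi[t] += (float)add; break; }
            if (bi[t] == 0) { bi[t] = bj[s]; wi[t] = (float)add; break; }
          }
          if (t == K) {
            // slots full: add to the smallest-weight slot
            int tmin = 0;
            for (int u = 1; u < K; ++u) if (wi[u] < wi[tmin]) tmin = u;
            wi[tmin] += (float)add;
          }
        }
      }
    }
    double rw = r[i] * dV;
    for (int s = 0; s < K; ++s) {
      if (bi[s] == 0) break;
      if (bi[s] >= 1 && bi[s] <= nb) pop[bi[s] - 1] += rw * wi[s];
    }
  }
  return pop;
}
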