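// [[Rcpp::depends(RcppArmadillo)]]
#include "qc_common.h"

using namespace Rcpp;

// Gauss-Legendre nodes/weights on [-1,1]
static void gauleg(int n, std::vector<double>& x, std::vector<double>& w) {
  x.resize(n); w.resize(n);
  for (int i = 0; i < (n + 1) / 2; ++i) {
    double z = std::cos(M_PI * (i + 0.75) / (n + 0.5)), z1, pp;
    do {
      double p1 = 1.0, p2 = 0.0;
      for (int j = 0; j < n; ++j) {
        double p3 = p2; p2 = p1;
        p1 = ((2.0 * j + 1.0) * z * p2 - j * p3) / (j + 1.0);
      }
      pp = n * (z * p1 - p2) / (z * z - 1.0);
      z1 = z; z = z1 - p1 / pp;
    } while (std::fabs(z - z1) > 1e-14);
    x[i] = -z; x[n - 1 - i] = z;
    w[i] = 2.0 / ((1.0 - z * z) * pp * pp);
    w[n - 1 - i] = w[i];
  }
}

static inline double becke_step(double mu) {
  for (int k = 0; k < 3; ++k) mu = 1.5 * mu - 0.5 * mu * mu * mu;
  return 0.5 * (1.0 - mu);
}

// Becke molecular integration grid with Mura-Knowles radial scheme and
// a pruned Gauss-Legendre x uniform-phi angular product grid.
// bragg: per-atom size parameter (Bohr).
// [[Rcpp::export(name = ".cpp_becke_grid")]]
List becke_grid(arma::mat coords, arma::vec bragg, int nrad, int ntheta) {
  int natom = coords.n_rows;
  // precompute pairwise distances and size-adjustment parameters
  arma::mat Rij(natom, natom, arma::fill::zeros);
  arma::mat aij(natom, natom, arma::fill::zeros);
  for (int i = 0; i < natom; ++i)
    for (int j = 0; j < natom; ++j) {
      if (i == j) continue;
      Rij(i, j) = arma::norm(coords.row(i) - coords.row(j));
      double chi = bragg(i) / bragg(j);
      double u = (chi - 1.0) / (chi + 1.0);
      double a = u / (u * u - 1.0);
      if (a > 0.45) a = 0.45;
      if (a < -0.45) a = -0.45;
      aij(i, j) = a;
    }
  std::vector<double> px, pw, gx[3], gw[3];
  int nth[3] = {std::max(6, ntheta / 3), std::max(8, (2 * ntheta) / 3), ntheta};
  for (int k = 0; k < 3; ++k) gauleg(nth[k], gx[k], gw[k]);
  const double alpha = 5.0;
  std::vector<double> P(natom);
  std::vector<double> X, Y, Zv, Wv;
  for (int A = 0; A < natom; ++A) {
    double rb = bragg(A);
    for (int ir = 0; ir < nrad; ++ir) {
      double x = (ir + 0.5) / nrad;
      double x3 = x * x * x;
      double r = -alpha * std::log(1.0 - x3);
      double drdx = alpha * 3.0 * x * x / (1.0 - x3);
      double wrad = (1.0 / nrad) * drdx * r * r;
      int reg = (r < 0.3 * rb) ? 0 : ((r < 1.0 * rb) ? 1 : 2);
      int nt = nth[reg];
      int nphi = 2 * nt;
      double wphi = 2.0 * M_PI / nphi;
      for (int it = 0; it < nt; ++it) {
        double ct = gx[reg][it], st = std::sqrt(1.0 - ct * ct);
        double wt = gw[reg][it];
        for (int ip = 0; ip < nphi; ++ip) {
          double phi = (ip + 0.5) * wphi / 1.0 * 1.0;
          double sx = st * std::cos(phi * 1.0);
          double sy = st * std::sin(phi);
          double pt[3] = {coords(A,0) + r * sx, coords(A,1) + r * sy,
                          coords(A,2) + r * ct};
          double w0 = wrad * wt * wphi;
          if (w0 < 1e-16) continue;
          // Becke partition
          double psum = 0.0, pA = 0.0;
          for (int i = 0; i < natom; ++i) {
            double ri = std::sqrt(
              (pt[0]-coords(i,0))*(pt[0]-coords(i,0)) +
              (pt[1]-coords(i,1))*(pt[1]-coords(i,1)) +
              (pt[2]-coords(i,2))*(pt[2]-coords(i,2)));
            P[i] = ri;
          }
          for (int i = 0; i < natom; ++i) {
            double cell = 1.0;
            for (int j = 0; j < natom; ++j) {
              if (i == j) continue;
              double mu = (P[i] - P[j]) / Rij(i, j);
              double nu = mu + aij(i, j) * (1.0 - mu * mu);
              cell *= becke_step(nu);
              if (cell < 1e-14) break;
            }
            psum += cell;
            if (i == A) pA = cell;
          }
          if (psum <= 0.0) continue;
          double w = w0 * pA / psum;
          if (w < 1e-14) continue;
          X.push_back(pt[0]); Y.push_back(pt[1]); Zv.push_back(pt[2]);
          Wv.push_back(w);
        }
      }
    }
  }
  int np = X.size();
  arma::mat pts(np, 3);
  arma::vec w(np);
  for (int i = 0; i < np; ++i) {
    pts(i, 0) = X[i]; pts(i, 1) = Y[i]; pts(i, 2) = Zv[i];
    w(i) = Wv[i];
  }
  (void)px; (void)pw;
  return List::create(_["points"] = pts, _["weights"] = w);
}
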