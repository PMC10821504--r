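// [[Rcpp::depends(RcppArmadillo)]]
#include "qc_common.h"
#include "md.h"

using namespace Rcpp;

// Gradient of Tr(D * (T + Vne)) - Tr(W * S) with respect to nuclear
// coordinates.  D: density, W: energy-weighted density (both symmetric,
// in the normalised basis).  coords/charges: nuclei.
// [[Rcpp::export(name = ".cpp_grad_1e")]]
arma::mat grad_1e(List basis, arma::mat D, arma::mat W, arma::mat coords,
                  arma::vec charges, int natom) {
  std::vector<Shell> sh = shells_from_R(basis);
  arma::mat grad(natom, 3, arma::fill::zeros);
  std::vector<std::array<int,3>> CA, CB;
  int ns = sh.size();
  for (int A = 0; A < ns; ++A)
    for (int B = 0; B <= A; ++B) {
      const Shell &a = sh[A], &b = sh[B];
      double f = (A == B) ? 1.0 : 2.0;
      bool same_center_ST = (a.atom == b.atom);
      cart_components(a.l, CA);
      cart_components(b.l, CB);
      int na = ncart(a.l), nb = ncart(b.l);
      double AB[3] = {a.R[0]-b.R[0], a.R[1]-b.R[1], a.R[2]-b.R[2]};
      double rab2 = AB[0]*AB[0]+AB[1]*AB[1]+AB[2]*AB[2];
      int Lab = a.l + b.l + 1;
      static thread_local std::vector<double> R, Rscr;
      int S = Lab + 1;
      auto rid = [&](int t, int u, int v) { return ((size_t)t * S + u) * S + v; };
      for (size_t ia = 0; ia < a.alpha.size(); ++ia)
        for (size_t ib = 0; ib < b.alpha.size(); ++ib) {
          double al = a.alpha[ia], be = b.alpha[ib];
          double p = al + be;
          double K = std::exp(-al * be / p * rab2);
          double cc = a.coef[ia] * b.coef[ib] * K;
          if (std::fabs(cc) < 1e-16) continue;
          double P[3], PA[3], PB[3];
          for (int t = 0; t < 3; ++t) {
            P[t] = (al * a.R[t] + be * b.R[t]) / p;
            PA[t] = P[t] - a.R[t];
            PB[t] = P[t] - b.R[t];
          }
          ETab E[3];
          for (int d = 0; d < 3; ++d)
            build_E(E[d], a.l + 1, b.l + 3, p, PA[d], PB[d], 1.0);
          double prefS = cc * std::pow(M_PI / p, 1.5);
          // ---- overlap + kinetic derivative (slot A; slot B = -A) ----
          if (!same_center_ST) {
            for (int pa = 0; pa < na; ++pa)
              for (int pb = 0; pb < nb; ++pb) {
                int I = a.offset + pa, J = b.offset + pb;
                double sc = a.scale[pa] * b.scale[pb];
                double dmat = D(I, J), wmat = W(I, J);
                if (std::fabs(dmat) < 1e-13 && std::fabs(wmat) < 1e-13)
                  continue;
                int ii[3] = {CA[pa][0], CA[pa][1], CA[pa][2]};
                int jj[3] = {CB[pb][0], CB[pb][1], CB[pb][2]};
                auto s1 = [&](int d, int i_, int j_) {
                  return E[d].at(i_, j_, 0);
                };
                auto t1 = [&](int d, int i_, int j_) {
                  double t = -2.0 * be * be * E[d].at(i_, j_ + 2, 0)
                           + be * (2.0 * j_ + 1.0) * E[d].at(i_, j_, 0);
                  if (j_ >= 2) t -= 0.5 * j_ * (j_ - 1.0) * E[d].at(i_, j_ - 2, 0);
                  return t;
                };
                for (int d = 0; d < 3; ++d) {
                  int e1 = (d + 1) % 3, e2 = (d + 2) % 3;
                  double Sx = s1(d, ii[d], jj[d]);
                  double Sy = s1(e1, ii[e1], jj[e1]);
                  double Sz = s1(e2, ii[e2], jj[e2]);
                  double Tx = t1(d, ii[d], jj[d]);
                  double Ty = t1(e1, ii[e1], jj[e1]);
                  double Tz = t1(e2, ii[e2], jj[e2]);
                  double dSx = 2.0 * al * s1(d, ii[d] + 1, jj[d]);
                  if (ii[d] > 0) dSx -= ii[d] * s1(d, ii[d] - 1, jj[d]);
                  double dTx = 2.0 * al * t1(d, ii[d] + 1, jj[d]);
                  if (ii[d] > 0) dTx -= ii[d] * t1(d, ii[d] - 1, jj[d]);
                  double dS = prefS * dSx * Sy * Sz;
                  double dT = prefS * (dTx * Sy * Sz + dSx * (Ty * Sz + Sy * Tz));
                  double contrib = f * sc * (dmat * dT - wmat * dS);
                  grad(a.atom, d) += contrib;
                  grad(b.atom, d) -= contrib;
                }
              }
          }
          // ---- nuclear attraction derivative ----
          double prefV = cc * 2.0 * M_PI / p;
          for (arma::uword nucl = 0; nucl < charges.n_elem; ++nucl) {
            double C[3] = {coords(nucl,0), coords(nucl,1), coords(nucl,2)};
            R.resize((size_t)S * S * S);
            Rscr.resize((size_t)(Lab + 1) * S * S * S);
            build_R(R.data(), Rscr.data(), Lab, p, P[0]-C[0], P[1]-C[1], P[2]-C[2]);
            double Z = charges(nucl);
            for (int pa = 0; pa < na; ++pa)
              for (int pb = 0; pb < nb; ++pb) {
                int I = a.offset + pa, J = b.offset + pb;
                double dmat = D(I, J);
                if (std::fabs(dmat) < 1e-13) continue;
                double sc = a.scale[pa] * b.scale[pb];
                int ii[3] = {CA[pa][0], CA[pa][1], CA[pa][2]};
                int jj[3] = {CB[pb][0], CB[pb][1], CB[pb][2]};
                // Hermite sum with bra powers (per dimension) ix/jx
                auto vsum = [&](int i0, int j0, int i1, int j1, int i2, int j2)
                    -> double {
                  double sum = 0.0;
                  for (int t = 0; t <= i0 + j0; ++t) {
                    double ex = E[0].at(i0, j0, t);
                    if (ex == 0.0) continue;
                    for (int u = 0; u <= i1 + j1; ++u) {
                      double ey = E[1].at(i1, j1, u);
                      if (ey == 0.0) continue;
                      for (int v = 0; v <= i2 + j2; ++v) {
                        double ez = E[2].at(i2, j2, v);
                        if (ez == 0.0) continue;
                        sum += ex * ey * ez * R[rid(t, u, v)];
                      }
                    }
                  }
                  return sum;
                };
                int bi[3] = {ii[0], ii[1], ii[2]};
                int bj[3] = {jj[0], jj[1], jj[2]};
                auto call = [&]() {
                  return vsum(bi[0], bj[0], bi[1], bj[1], bi[2], bj[2]);
                };
                for (int d = 0; d < 3; ++d) {
                  bi[d] += 1;
                  double upA = call();
                  bi[d] -= 1;
                  double dnA = 0.0;
                  if (ii[d] > 0) { bi[d] -= 1; dnA = call(); bi[d] += 1; }
                  double dA = 2.0 * al * upA - ii[d] * dnA;
                  bj[d] += 1;
                  double upB = call();
                  bj[d] -= 1;
                  double dnB = 0.0;
                  if (jj[d] > 0) { bj[d] -= 1; dnB = call(); bj[d] += 1; }
                  double dB = 2.0 * be * upB - jj[d] * dnB;
                  double w = -Z * prefV * f * sc * dmat;
                  grad(a.atom, d) += w * dA;
                  grad(b.atom, d) += w * dB;
                  grad(nucl, d) -= w * (dA + dB);
                }
              }
          }
        }
    }
  return grad;
}

// Nuclear repulsion energy and gradient
// [[Rcpp::export(name = ".cpp_nuc_rep")]]
List nuc_rep(arma::mat coords, arma::vec charges) {
  int n = coords.n_rows;
  double E = 0.0;
  arma::mat g(n, 3, arma::fill::zeros);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double d[3] = {coords(i,0)-coords(j,0), coords(i,1)-coords(j,1),
                     coords(i,2)-coords(j,2)};
      double r2 = d[0]*d[0] + d[1]*d[1] + d[2]*d[2];
      double r = std::sqrt(r2);
      double zz = charges(i) * charges(j);
      E += zz / r;
      for (int k = 0; k < 3; ++k) {
        double gv = -zz * d[k] / (r2 * r);
        g(i, k) += gv;
        g(j, k) -= gv;
      }
    }
  return List::create(_["E"] = E, _["grad"] = g);
}
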