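// [[Rcpp::depends(RcppArmadillo)]]
#include "qc_common.h"
#include "md.h"

using namespace Rcpp;

// 1D contracted overlap helper used for kinetic assembly
static inline double s1d(const ETab& E, int i, int j) { return E.at(i, j, 0); }

// Compute overlap and kinetic matrices in one pass.
// [[Rcpp::export(name = ".cpp_int1e_ovl_kin")]]
List int1e_ovl_kin(List basis) {
  std::vector<Shell> sh = shells_from_R(basis);
  int n = nbf_total(sh);
  arma::mat S(n, n, arma::fill::zeros), T(n, n, arma::fill::zeros);
  std::vector<std::array<int,3>> ca, cb;
  for (size_t A = 0; A < sh.size(); ++A) {
    for (size_t B = 0; B <= A; ++B) {
      const Shell &a = sh[A], &b = sh[B];
      cart_components(a.l, ca);
      cart_components(b.l, cb);
      int na = ncart(a.l), nb = ncart(b.l);
      std::vector<double> Sblk((size_t)na * nb, 0.0), Tblk((size_t)na * nb, 0.0);
      double AB[3] = {a.R[0] - b.R[0], a.R[1] - b.R[1], a.R[2] - b.R[2]};
      double rab2 = AB[0]*AB[0] + AB[1]*AB[1] + AB[2]*AB[2];
      for (size_t ia = 0; ia < a.alpha.size(); ++ia)
        for (size_t ib = 0; ib < b.alpha.size(); ++ib) {
          double al = a.alpha[ia], be = b.alpha[ib];
          double p = al + be, mu = al * be / p;
          double K = std::exp(-mu * rab2);
          if (K < 1e-16) continue;
          double P[3], PA[3], PB[3];
          for (int d = 0; d < 3; ++d) {
            P[d] = (al * a.R[d] + be * b.R[d]) / p;
            PA[d] = P[d] - a.R[d];
            PB[d] = P[d] - b.R[d];
          }
          // need j up to b.l+2 for kinetic
          ETab Ex, Ey, Ez;
          build_E(Ex, a.l, b.l + 2, p, PA[0], PB[0], 1.0);
          build_E(Ey, a.l, b.l + 2, p, PA[1], PB[1], 1.0);
          build_E(Ez, a.l, b.l + 2, p, PA[2], PB[2], 1.0);
          double pref = K * a.coef[ia] * b.coef[ib] *
                        std::pow(M_PI / p, 1.5);
          for (int pa = 0; pa < na; ++pa)
            for (int pb = 0; pb < nb; ++pb) {
              int i = ca[pa][0], jj = ca[pa][1], k = ca[pa][2];
              int l = cb[pb][0], m = cb[pb][1], nn = cb[pb][2];
              double sx = s1d(Ex, i, l), sy = s1d(Ey, jj, m), sz = s1d(Ez, k, nn);
              double sval = sx * sy * sz;
              // kinetic 1D pieces: T(i,j) = -2 be^2 S(i,j+2)
              //   + be (2j+1) S(i,j) - j(j-1)/2 S(i,j-2)
              auto t1d = [&](const ETab& E, int i_, int j_) {
                double t = -2.0 * be * be * E.at(i_, j_ + 2, 0)
                         + be * (2.0 * j_ + 1.0) * E.at(i_, j_, 0);
                if (j_ >= 2) t -= 0.5 * j_ * (j_ - 1.0) * E.at(i_, j_ - 2, 0);
                return t;
              };
              double tx = t1d(Ex, i, l), ty = t1d(Ey, jj, m), tz = t1d(Ez, k, nn);
              double tval = tx * sy * sz + sx * ty * sz + sx * sy * tz;
              Sblk[(size_t)pa * nb + pb] += pref * sval;
              Tblk[(size_t)pa * nb + pb] += pref * tval;
            }
        }
      for (int pa = 0; pa < na; ++pa)
        for (int pb = 0; pb < nb; ++pb) {
          double sc = a.scale[pa] * b.scale[pb];
          int I = a.offset + pa, J = b.offset + pb;
          S(I, J) = Sblk[(size_t)pa * nb + pb] * sc;
          T(I, J) = Tblk[(size_t)pa * nb + pb] * sc;
          S(J, I) = S(I, J);
          T(J, I) = T(I, J);
        }
    }
  }
  return List::create(_["S"] = S, _["T"] = T);
}

// Nuclear attraction matrix: V_mn = sum_C (-Z_C) <m| 1/|r-C| |n>
// charges at centers; also reusable for ESP integrals (unit charge).
static void attraction_block(const Shell& a, const Shell& b,
                             const double* C, double Z,
                             std::vector<double>& out) {
  std::vector<std::array<int,3>> ca, cb;
  cart_components(a.l, ca);
  cart_components(b.l, cb);
  int na = ncart(a.l), nb = ncart(b.l);
  double AB[3] = {a.R[0] - b.R[0], a.R[1] - b.R[1], a.R[2] - b.R[2]};
  double rab2 = AB[0]*AB[0] + AB[1]*AB[1] + AB[2]*AB[2];
  int L = a.l + b.l;
  static thread_local std::vector<double> R, Rscr;
  for (size_t ia = 0; ia < a.alpha.size(); ++ia)
    for (size_t ib = 0; ib < b.alpha.size(); ++ib) {
      double al = a.alpha[ia], be = b.alpha[ib];
      double p = al + be, mu = al * be / p;
      double K = std::exp(-mu * rab2);
      if (K < 1e-16) continue;
      double P[3], PA[3], PB[3];
      for (int d = 0; d < 3; ++d) {
        P[d] = (al * a.R[d] + be * b.R[d]) / p;
        PA[d] = P[d] - a.R[d];
        PB[d] = P[d] - b.R[d];
      }
      ETab Ex, Ey, Ez;
      build_E(Ex, a.l, b.l, p, PA[0], PB[0], 1.0);
      build_E(Ey, a.l, b.l, p, PA[1], PB[1], 1.0);
      build_E(Ez, a.l, b.l, p, PA[2], PB[2], 1.0);
      int S = L + 1;
      R.resize((size_t)S * S * S);
      Rscr.resize((size_t)(L + 1) * S * S * S);
      build_R(R.data(), Rscr.data(), L, p, P[0] - C[0], P[1] - C[1], P[2] - C[2]);
      auto rid = [&](int t, int u, int v) { return ((size_t)t * S + u) * S + v; };
      double pref = -Z * K * a.coef[ia] * b.coef[ib] * 2.0 * M_PI / p;
      for (int pa = 0; pa < na; ++pa)
        for (int pb = 0; pb < nb; ++pb) {
          int i = ca[pa][0], jj = ca[pa][1], k = ca[pa][2];
          int l = cb[pb][0], m = cb[pb][1], nn = cb[pb][2];
          double sum = 0.0;
          for (int t = 0; t <= i + l; ++t) {
            double ex = Ex.at(i, l, t);
            if (ex == 0.0) continue;
            for (int u = 0; u <= jj + m; ++u) {
              double ey = Ey.at(jj, m, u);
              if (ey == 0.0) continue;
              for (int v = 0; v <= k + nn; ++v) {
                double ez = Ez.at(k, nn, v);
                if (ez == 0.0) continue;
                sum += ex * ey * ez * R[rid(t, u, v)];
              }
            }
          }
          out[(size_t)pa * nb + pb] += pref * sum;
        }
    }
}

// [[Rcpp::export(name = ".cpp_int1e_nuc")]]
arma::mat int1e_nuc(List basis, arma::mat coords, arma::vec charges) {
  std::vector<Shell> sh = shells_from_R(basis);
  int n = nbf_total(sh);
  arma::mat V(n, n, arma::fill::zeros);
  for (size_t A = 0; A < sh.size(); ++A)
    for (size_t B = 0; B <= A; ++B) {
      const Shell &a = sh[A], &b = sh[B];
      int na = ncart(a.l), nb = ncart(b.l);
      std::vector<double> blk((size_t)na * nb, 0.0);
      for (arma::uword c = 0; c < charges.n_elem; ++c) {
        double C[3] = {coords(c, 0), coords(c, 1), coords(c, 2)};
        attraction_block(a, b, C, charges(c), blk);
      }
      for (int pa = 0; pa < na; ++pa)
        for (int pb = 0; pb < nb; ++pb) {
          double sc = a.scale[pa] * b.scale[pb];
          int I = a.offset + pa, J = b.offset + pb;
          V(I, J) = blk[(size_t)pa * nb + pb] * sc;
          V(J, I) = V(I, J);
        }
    }
  return V;
}

// Electrostatic potential of the electron density at arbitrary points:
// Vel(r) = sum_mn D_mn <m|1/|r-r'||n>  (positive quantity; caller
// combines with nuclear part).  Points in Bohr, rows of `pts`.
// [[Rcpp::export(name = ".cpp_esp_points")]]
arma::vec esp_points(List basis, arma::mat D, arma::mat pts) {
  std::vector<Shell> sh = shells_from_R(basis);
  arma::vec out(pts.n_rows, arma::fill::zeros);
  // Pre-scale density by per-component normalisation so blocks can be
  // contracted raw.
  int n = nbf_total(sh);
  arma::vec scl(n);
  for (auto& s : sh)
    for (int c = 0; c < ncart(s.l); ++c) scl(s.offset + c) = s.scale[c];
  arma::mat Ds = D;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) Ds(i, j) *= scl(i) * scl(j);
  for (size_t A = 0; A < sh.size(); ++A)
    for (size_t B = 0; B <= A; ++B) {
      const Shell &a = sh[A], &b = sh[B];
      int na = ncart(a.l), nb = ncart(b.l);
      double fac = (A == B) ? 1.0 : 2.0;
      std::vector<double> blk((size_t)na * nb);
      for (arma::uword p = 0; p < pts.n_rows; ++p) {
        double C[3] = {pts(p, 0), pts(p, 1), pts(p, 2)};
        std::fill(blk.begin(), blk.end(), 0.0);
        attraction_block(a, b, C, -1.0, blk);  // -Z=+1 => plain integral
        double acc = 0.0;
        for (int pa = 0; pa < na; ++pa)
          for (int pb = 0; pb < nb; ++pb)
            acc += Ds(a.offset + pa, b.offset + pb) * blk[(size_t)pa * nb + pb];
        out(p) += fac * acc;
      }
    }
  return out;
}
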