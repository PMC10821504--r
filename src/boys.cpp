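#include "qc_common.h"

// Boys function F_m(T) = int_0^1 t^(2m) exp(-T t^2) dt.
// Series for small/moderate T (downward recursion from a converged
// series at mmax), asymptotic + upward recursion for large T.
void boys(int m, double T, double* F) {
  if (T < 1e-13) {
    for (int k = 0; k <= m; ++k) F[k] = 1.0 / (2.0 * k + 1.0);
    return;
  }
  if (m == 0) {
    // closed form, fast path for the dominant (ss|ss) class
    double sq = std::sqrt(T);
    F[0] = 0.5 * std::sqrt(M_PI) * std::erf(sq) / sq;
    return;
  }
  if (T >= (double)m || T > 28.0) {
    // upward recursion from the closed-form F0 amplifies errors by at
    // most (2k-1)/(2T) per step, < 1 whenever T >= m: stable here
    double sq = std::sqrt(T);
    F[0] = 0.5 * std::sqrt(M_PI) * std::erf(sq) / sq;
    double expT = (T > 700.0) ? 0.0 : std::exp(-T);
    double o2T = 0.5 / T;
    for (int k = 1; k <= m; ++k)
      F[k] = ((2.0 * k - 1.0) * F[k - 1] - expT) * o2T;
    return;
  }
  // series at the highest order, then stable downward recursion
  double expT = std::exp(-T);
  double sum = 0.0, term = 1.0 / (2.0 * m + 1.0);
  for (int i = 0; i < 200; ++i) {
    sum += term;
    term *= 2.0 * T / (2.0 * m + 2.0 * i + 3.0);
    if (term < 1e-16 * sum) break;
  }
  F[m] = expT * sum;
  for (int k = m - 1; k >= 0; --k)
    F[k] = (2.0 * T * F[k + 1] + expT) / (2.0 * k + 1.0);
}

std::vector<Shell> shells_from_R(const Rcpp::List& basis) {
  std::vector<Shell> out;
  int offset = 0;
  for (int i = 0; i < basis.size(); ++i) {
    Rcpp::List s = basis[i];
    Shell sh;
    sh.l = Rcpp::as<int>(s["l"]);
    sh.atom = Rcpp::as<int>(s["atom"]) - 1;
    Rcpp::NumericVector R = s["center"];
    sh.R[0] = R[0]; sh.R[1] = R[1]; sh.R[2] = R[2];
    sh.alpha = Rcpp::as<std::vector<double>>(s["alpha"]);
    sh.coef = Rcpp::as<std::vector<double>>(s["coef"]);
    sh.scale = Rcpp::as<std::vector<double>>(s["scale"]);
    sh.offset = offset;
    offset += ncart(sh.l);
    // screening radius: solve max_k |c_k| r^l exp(-a_min r^2) = 1e-12
    double amin = sh.alpha[0], cmax = 0.0;
    for (size_t k = 0; k < sh.alpha.size(); ++k) {
      amin = std::min(amin, sh.alpha[k]);
      cmax = std::max(cmax, std::fabs(sh.coef[k]) * (sh.alpha.size() > 0 ? 1.0 : 1.0));
    }
    double r = 1.0;
    for (int it = 0; it < 60; ++it) {
      double val = cmax * std::pow(r, sh.l) * std::exp(-amin * r * r);
      if (val > 1e-12) r += 0.5; else break;
    }
    sh.rcut2 = r * r;
    out.push_back(sh);
  }
  return out;
}

int nbf_total(const std::vector<Shell>& sh) {
  int n = 0;
  for (auto& s : sh) n += ncart(s.l);
  return n;
}
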