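#ifndef MOLDFT_MD_H
#define MOLDFT_MD_H

#include "qc_common.h"

// McMurchie-Davidson Hermite expansion coefficients for one dimension,
// fixed-capacity (stack) storage.  E(i,j,t), i<=imax, j<=jmax, t<=i+j.
// Capacity: i,j up to 5; t up to 11.
struct ETab {
  int imax, jmax;
  double v[6 * 6 * 12];
  inline double at(int i, int j, int t) const {
    if (t < 0 || t > i + j) return 0.0;
    return v[(i * 6 + j) * 12 + t];
  }
  inline double raw(int i, int j, int t) const {
    return v[(i * 6 + j) * 12 + t];
  }
};

inline void build_E(ETab& E, int imax, int jmax, double p, double PA,
                    double PB, double K) {
  E.imax = imax; E.jmax = jmax;
  const double o2p = 0.5 / p;
  auto idx = [](int i, int j, int t) { return (i * 6 + j) * 12 + t; };
  // zero the whole table: recursions legitimately read one entry past
  // the t <= i+j triangle, which must be 0
  std::fill(E.v, E.v + 6 * 6 * 12, 0.0);
  E.v[idx(0, 0, 0)] = K;
  for (int i = 1; i <= imax; ++i)
    for (int t = 0; t <= i; ++t) {
      double val = 0.0;
      if (t > 0) val += o2p * E.v[idx(i - 1, 0, t - 1)];
      val += PA * E.v[idx(i - 1, 0, t)];
      if (t + 1 <= i - 1) val += (t + 1) * E.v[idx(i - 1, 0, t + 1)];
      E.v[idx(i, 0, t)] = val;
    }
  for (int j = 1; j <= jmax; ++j)
    for (int i = 0; i <= imax; ++i)
      for (int t = 0; t <= i + j; ++t) {
        double val = 0.0;
        if (t > 0) val += o2p * E.v[idx(i, j - 1, t - 1)];
        val += PB * E.v[idx(i, j - 1, t)];
        if (t + 1 <= i + j - 1) val += (t + 1) * E.v[idx(i, j - 1, t + 1)];
        E.v[idx(i, j, t)] = val;
      }
}

// Hermite Coulomb integrals R^0_{tuv}, t+u+v <= L, composite exponent
// p, displacement (X,Y,Z).  Output in caller buffer R with stride
// S=L+1: R[(t*S+u)*S+v].  scratch must hold (L+1)*S*S*S doubles.
inline void build_R(double* R, double* scratch, int L, double p,
                    double X, double Y, double Z) {
  const int S = L + 1;
  const size_t SS = (size_t)S * S * S;
  double T = p * (X * X + Y * Y + Z * Z);
  double F[24];
  boys(L, T, F);
  if (L == 0) { R[0] = F[0]; return; }
  if (L == 1) {
    // R indexed with stride 2: (t*2+u)*2+v
    double m2pF1 = -2.0 * p * F[1];
    R[0] = F[0];          // (0,0,0)
    R[1] = Z * m2pF1;     // (0,0,1)
    R[2] = Y * m2pF1;     // (0,1,0)
    R[4] = X * m2pF1;     // (1,0,0)
    return;
  }
  auto id = [S](int t, int u, int v) { return ((size_t)t * S + u) * S + v; };
  // layer n stored at scratch + n*SS; layer 0 goes straight to R
  for (int n = L; n >= 0; --n) {
    double* lay = (n == 0) ? R : scratch + (size_t)n * SS;
    double pw = 1.0;
    for (int k = 0; k < n; ++k) pw *= -2.0 * p;
    lay[id(0, 0, 0)] = pw * F[n];
    const double* up = scratch + (size_t)(n + 1) * SS;
    int lmax = L - n;
    for (int s = 1; s <= lmax; ++s)
      for (int t = 0; t <= s; ++t)
        for (int u = 0; u <= s - t; ++u) {
          int v = s - t - u;
          double val;
          if (t > 0) {
            val = X * up[id(t - 1, u, v)];
            if (t > 1) val += (t - 1) * up[id(t - 2, u, v)];
          } else if (u > 0) {
            val = Y * up[id(t, u - 1, v)];
            if (u > 1) val += (u - 1) * up[id(t, u - 2, v)];
          } else {
            val = Z * up[id(t, u, v - 1)];
            if (v > 1) val += (v - 1) * up[id(t, u, v - 2)];
          }
          lay[id(t, u, v)] = val;
        }
  }
}

// Precomputed data for one primitive pair of a shell pair
struct PrimPair {
  double p;        // alpha + beta
  double c;        // coef_a * coef_b * exp(-mu r2)  (includes K factors)
  double al, be;   // exponents
  double qp;       // primitive Cauchy-Schwarz bound sqrt(max (ab|ab))
  double P[3];
  ETab Ex, Ey, Ez;
};

// Shell-pair with cached Hermite expansion tables
struct ShellPair {
  int A, B;
  std::vector<PrimPair> prims;
};

// build pair data; imax/jmax extended by `extra` for derivative use
inline void build_pair(const Shell& a, const Shell& b, int extra,
                       ShellPair& sp) {
  sp.prims.clear();
  double AB[3] = {a.R[0]-b.R[0], a.R[1]-b.R[1], a.R[2]-b.R[2]};
  double rab2 = AB[0]*AB[0]+AB[1]*AB[1]+AB[2]*AB[2];
  for (size_t ia = 0; ia < a.alpha.size(); ++ia)
    for (size_t ib = 0; ib < b.alpha.size(); ++ib) {
      double al = a.alpha[ia], be = b.alpha[ib];
      double p = al + be;
      double K = std::exp(-al * be / p * rab2);
      double c = a.coef[ia] * b.coef[ib] * K;
      if (std::fabs(c) < 1e-16) continue;
      PrimPair pp;
      pp.p = p; pp.c = c; pp.al = al; pp.be = be;
      double PA[3], PB[3];
      for (int d = 0; d < 3; ++d) {
        pp.P[d] = (al * a.R[d] + be * b.R[d]) / p;
        PA[d] = pp.P[d] - a.R[d];
        PB[d] = pp.P[d] - b.R[d];
      }
      build_E(pp.Ex, a.l + extra, b.l + extra, p, PA[0], PB[0], 1.0);
      build_E(pp.Ey, a.l + extra, b.l + extra, p, PA[1], PB[1], 1.0);
      build_E(pp.Ez, a.l + extra, b.l + extra, p, PA[2], PB[2], 1.0);
      pp.qp = 1e10;  // set by set_prim_schwarz (safe default: no skip)
      sp.prims.push_back(pp);
    }
}

#endif
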