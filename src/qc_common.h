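#ifndef MOLDFT_QC_COMMON_H
#define MOLDFT_QC_COMMON_H

#include <RcppArmadillo.h>
#include <vector>
#include <cmath>

// A contracted Cartesian Gaussian shell.  Contraction coefficients are
// expected to already include primitive normalisation and the overall
// contraction normalisation for the (l,0,0) component; per-component
// scale factors are carried separately (scale has ncart(l) entries).
struct Shell {
  int l;
  int atom;           // 0-based atom index
  double R[3];        // centre, Bohr
  std::vector<double> alpha;
  std::vector<double> coef;
  std::vector<double> scale;  // per Cartesian component normalisation
  int offset;         // first basis-function index of this shell
  double rcut2;       // squared screening radius
};

inline int ncart(int l) { return (l + 1) * (l + 2) / 2; }

// Cartesian component powers in fixed lexicographic order
inline void cart_components(int l, std::vector<std::array<int,3>>& comps) {
  comps.clear();
  for (int i = l; i >= 0; --i)
    for (int j = l - i; j >= 0; --j)
      comps.push_back({i, j, l - i - j});
}

inline double dfact(int n) { // (2n-1)!! with dfact(0)=1
  double r = 1.0;
  for (int k = 2 * n - 1; k > 1; k -= 2) r *= k;
  return r;
}

std::vector<Shell> shells_from_R(const Rcpp::List& basis);
int nbf_total(const std::vector<Shell>& sh);

// Boys function F_0..F_m(T), results in F[0..m]
void boys(int m, double T, double* F);

#endif
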