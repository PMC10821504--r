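// [[Rcpp::depends(RcppArmadillo)]]
#include "qc_common.h"
#include "eval_basis.h"

using namespace Rcpp;

// ---------------------------------------------------------------------
// Pointwise exchange-correlation evaluation.
// Spin-resolved inputs: ra, rb (densities), gaa = |grad ra|^2,
// gab = grad ra . grad rb, gbb.  Output: f (energy density per volume)
// and partial derivatives d f / d(ra, rb, gaa, gab, gbb).
// Pieces: Slater exchange, B88 gradient correction, VWN functional III
// (RPA parametrisation, the Gaussian-program B3LYP convention), LYP.
// Mixing coefficients are supplied by the caller.
// ---------------------------------------------------------------------

static const double CXS = 0.9305257363491; // (3/2)(3/(4 pi))^(1/3)

static inline void slater_spin(double r, double& f, double& dr) {
  double r13 = std::cbrt(r);
  f = -CXS * r * r13;
  dr = -CXS * (4.0 / 3.0) * r13;
}

static inline void b88_spin(double r, double g, double& f, double& dr,
                            double& dg) {
  if (r < 1e-13) { f = dr = dg = 0.0; return; }
  if (g < 1e-20) {
    double x1 = std::pow(r, -4.0 / 3.0);
    f = -0.0042 * g * x1;
    dr = 0.0056 * g * x1 / r;
    dg = -0.0042 * x1;
    return;
  }
  const double x0 = sqrt(g);
  const double x1 = pow(r, -4.0 / 3.0);
  const double x2 = x0 * x1;
  const double x3 = asinh(x2);
  const double x4 = x2 * x3;
  const double x5 = g * x1;
  const double x6 = 1.0 / (63 * x4 + 2500);
  const double x7 = x1 / sqrt(g / pow(r, 8.0 / 3.0) + 1);
  const double x8 = x1 * x6;
  f = -21.0 / 5000.0 * x5 / ((63.0 / 2500.0) * x4 + 1);
  dr = 14 * g * x6 * (-63 * x8 * (g * x7 + x0 * x3) + 1) / pow(r, 7.0 / 3.0);
  dg = (21.0 / 4.0) * x8 * (63 * x5 * x6 * (x7 + x3 / x0) - 2);
}

static inline void vwn3_eval(double ra, double rb, double& f, double& dra,
                             double& drb) {
  const double x0 = ra + rb;
  const double x1 = pow(2, 2.0 / 3.0);
  const double x2 = pow(3, 1.0 / 6.0);
  const double x3 = pow(M_PI, -1.0 / 6.0);
  const double x4 = x1 * x2 * x3;
  const double x5 = x4 / pow(x0, 1.0 / 6.0);
  const double x6 = x5 + 13.071999999999999;
  const double x7 = atan(0.044899888641576798 / x6);
  const double x8 = cbrt(6) / cbrt(M_PI);
  const double x9 = x8 / cbrt(x0);
  const double x10 = 1.0 / (13.071999999999999 * x5 + x9 + 85.439599999999999);
  const double x11 = log(x10 * x9);
  const double x12 = x5 + 0.81857199999999997;
  const double x13 = log((1.0 / 2.0) * x10 * pow(x12, 2));
  const double x14 = x5 + 20.123100000000001;
  const double x15 = 1.0 / (20.123100000000001 * x5 + x9 + 203.15600000000001);
  const double x16 = x5 + 1.486588;
  const double x17 = 0.031090699999999999 * x11 + 0.0044313737677495373 * x13 +
      20.521972937705183 * x7 -
      0.0026673100072733152 * log((1.0 / 2.0) * x15 * pow(x16, 2)) -
      0.015545349999999999 * log(x15 * x9) -
      0.61881802979061773 * atan(1.1716852777089715 / x14);
  const double x18 = 1.0 / (1 - cbrt(2));
  const double x19 = 1.0 / x0;
  const double x20 = x19 * (ra - rb);
  const double x21 = x20 + 1;
  const double x22 = pow(x21, 4.0 / 3.0);
  const double x23 = x20 - 1;
  const double x24 = -x23;
  const double x25 = x18 * (x22 + pow(x24, 4.0 / 3.0) - 2);
  const double x26 = x17 * x25;
  const double x27 = cbrt(x24);
  const double x28 = 4 * x17 * x18 * x19;
  const double x29 = 1.0 / x12;
  const double x30 = pow(x0, -7.0 / 6.0);
  const double x31 = x30 * x4;
  const double x32 = x8 / pow(x0, 4.0 / 3.0);
  const double x33 = 6.5359999999999996 * x31 + x32;
  const double x34 = x10 * x33;
  const double x35 = x12 * x34;
  const double x36 = pow(x6, -2);
  const double x37 = 1.0 / (0.002016000000025997 * x36 + 1);
  const double x38 = pow(x14, -2);
  const double x39 = x15 * (10.06155 * x31 + x32);
  const double x40 = -0.062181399999999998 * x19 +
      3 * x25 * (0.15357238326806921 * x1 * x2 * x3 * x30 * x36 * x37 +
                 0.010363566666666666 * x10 * x33 -
                 0.0051817833333333329 * x19 +
                 x29 * (-0.0014771245892498458 * x31 +
                        0.0014771245892498458 * x35) -
                 0.12084332918108974 * x31 * x38 /
                     (1.3728463899999497 * x38 + 1) -
                 0.0051817833333333329 * x39 -
                 (0.00088910333575777166 * x16 * x39 -
                  0.00088910333575777166 * x31) / x16) +
      x29 * (-0.0088627475354990746 * x31 + 0.0088627475354990746 * x35) +
      0.92143429960841527 * x31 * x36 * x37 + 0.062181399999999998 * x34;
  const double x41 = 0.18654419999999999 * x11 + 0.026588242606497225 * x13 +
      3 * x26 + 123.13183762623109 * x7;
  f = (1.0 / 2.0) * x0 * (0.062181399999999998 * x11 +
      0.0088627475354990746 * x13 + x26 + 41.043945875410365 * x7);
  dra = (1.0 / 6.0) * x0 * (x23 * x28 * (-cbrt(x21) + x27) + x40) +
      (1.0 / 6.0) * x41;
  drb = (1.0 / 6.0) * x0 * (x28 * (x21 * x27 - x22) + x40) + (1.0 / 6.0) * x41;
}

static inline void lyp_eval(double ra, double rb, double gaa, double gab,
                            double gbb, double& f, double& dra, double& drb,
                            double& dgaa, double& dgab, double& dgbb) {
  const double x0 = ra + rb;
  const double x1 = pow(x0, -1.0 / 3.0);
  const double x2 = 0.34899999999999998 * x1;
  const double x3 = x2 + 1;
  const double x4 = 1.0 / x3;
  const double x5 = 1.0 / x0;
  const double x6 = 0.19672000000000001 * x5;
  const double x7 = rb * x6;
  const double x8 = pow(x0, -11.0 / 3.0);
  const double x9 = exp(-0.25330000000000003 * x1);
  const double x10 = pow(x0, 2);
  const double x11 = gaa + gbb;
  const double x12 = 2 * gab + x11;
  const double x13 = x10 * x12;
  const double x14 = -2 * x10;
  const double x15 = gaa * (3 * pow(rb, 2) + x14);
  const double x16 = gbb * (3 * pow(ra, 2) + x14);
  const double x17 = pow(6, 2.0 / 3.0) * pow(M_PI, 4.0 / 3.0);
  const double x18 = x1 * x4;
  const double x19 = 45 * x11;
  const double x20 = 1.7731000000000003 * x1 + 2.4430000000000001 * x18 - 47;
  const double x21 = gaa * ra;
  const double x22 = gbb * rb;
  const double x23 = x21 + x22;
  const double x24 = x5 * (0.25329999999999997 * x1 + x2 * x4 - 11);
  const double x25 = 5 * x12 * x20 -
      216 * x17 * (pow(ra, 8.0 / 3.0) + pow(rb, 8.0 / 3.0)) +
      x19 * (-0.028144444444444444 * x1 - 0.038777777777777772 * x18 + 5) +
      10 * x23 * x24;
  const double x26 = 7.2130666666666684e-5 * x25;
  const double x27 = rb * x26;
  const double x28 = 0.0086556800000000024 * x0 * x12;
  const double x29 = 288 * x17;
  const double x30 = x21 * x5 + x22 * x5;
  const double x31 = 5 * x24;
  const double x32 = pow(x0, -4.0 / 3.0);
  const double x33 = pow(x3, -2);
  const double x34 = x1 * x33;
  const double x35 = pow(x0, -7.0 / 3.0);
  const double x36 = -45 * x12 * x32 * (-0.015789018518518515 * x34 +
      0.045240740740740734 * x4 + 0.032835185185185189) +
      x19 * x32 * (-0.0022555740740740735 * x34 + 0.006462962962962962 * x4 +
                   0.0046907407407407401) +
      45 * x23 * x35 * (0.0045111481481481469 * x1 * x33 -
                        0.012925925925925924 * x4 - 0.0093814814814814802);
  const double x37 = ra * rb;
  const double x38 = 0.00014426133333333337 * x37;
  const double x39 = x8 * x9;
  const double x40 = x25 * x37;
  const double x41 = pow(x0, -5);
  const double x42 = -0.19672000000000001 * ra * rb / x10 +
      0.022885093333333332 * x35 * x37 * x4 -
      x4 * x41 * x9 * (0.00050347205333333334 * x13 +
                       0.00025173602666666667 * x15 +
                       0.00025173602666666667 * x16 +
                       8.3912008888888891e-6 * x40) -
      x41 * x9 * (0.00036541395733333335 * x13 + 0.00018270697866666668 * x15 +
                  0.00018270697866666668 * x16 + 6.090232622222223e-6 * x40) +
      x9 * (0.015868746666666669 * x13 + 0.0079343733333333347 * x15 +
            0.0079343733333333347 * x16 + 0.00026447911111111117 * x40) /
          pow(x0, 14.0 / 3.0);
  const double x43 = 0.75990000000000013 * x1 + 1.0469999999999999 * x18 - 1;
  const double x44 = x39 * x4;
  const double x45 = 0.0064917600000000009 * x44;
  f = x4 * (-ra * x7 + x8 * x9 * (ra * x27 + 0.0043278400000000012 * x13 +
      0.0021639200000000006 * x15 + 0.0021639200000000006 * x16));
  dra = x4 * (-x39 * (0.0086556800000000024 * gaa * x0 -
      0.0043278400000000012 * gbb * (ra - 2 * rb) - x27 - x28 -
      x38 * (-pow(ra, 5.0 / 3.0) * x29 + x31 * (gaa - x30) + x36)) - x42 - x7);
  drb = x4 * (-ra * x6 - x39 * (0.0043278400000000012 * gaa * (2 * ra - rb) +
      0.0086556800000000024 * gbb * x0 - ra * x26 - x28 -
      x38 * (-pow(rb, 5.0 / 3.0) * x29 + x31 * (gbb - x30) + x36)) - x42);
  dgaa = rb * x45 * ((1.0 / 9.0) * ra * (ra * x24 + x43) + rb);
  dgab = 0.00072130666666666676 * x44 * (12 * x10 + x20 * x37);
  dgbb = ra * x45 * (ra + (1.0 / 9.0) * rb * (rb * x24 + x43));
}

// combined functional: out = {f, dra, drb, dgaa, dgab, dgbb}
void xc_point(double ra, double rb, double gaa, double gab, double gbb,
              double cS, double cB, double cV, double cL, double out[6]) {
  for (int i = 0; i < 6; ++i) out[i] = 0.0;
  ra = std::max(ra, 1e-13);
  rb = std::max(rb, 1e-13);
  gaa = std::max(gaa, 0.0);
  gbb = std::max(gbb, 0.0);
  double f, d1, d2, d3, d4, d5;
  if (cS != 0.0) {
    slater_spin(ra, f, d1);
    out[0] += cS * f; out[1] += cS * d1;
    slater_spin(rb, f, d1);
    out[0] += cS * f; out[2] += cS * d1;
  }
  if (cB != 0.0) {
    b88_spin(ra, gaa, f, d1, d2);
    out[0] += cB * f; out[1] += cB * d1; out[3] += cB * d2;
    b88_spin(rb, gbb, f, d1, d2);
    out[0] += cB * f; out[2] += cB * d1; out[5] += cB * d2;
  }
  if (cV != 0.0) {
    vwn3_eval(ra, rb, f, d1, d2);
    out[0] += cV * f; out[1] += cV * d1; out[2] += cV * d2;
  }
  if (cL != 0.0) {
    lyp_eval(ra, rb, gaa, gab, gbb, f, d1, d2, d3, d4, d5);
    out[0] += cL * f; out[1] += cL * d1; out[2] += cL * d2;
    out[3] += cL * d3; out[4] += cL * d4; out[5] += cL * d5;
  }
}

// direct access for testing
// [[Rcpp::export(name = ".cpp_xc_point")]]
NumericVector xc_point_R(double ra, double rb, double gaa, double gab,
                         double gbb, NumericVector coef) {
  double out[6];
  xc_point(ra, rb, gaa, gab, gbb, coef[0], coef[1], coef[2], coef[3], out);
  return NumericVector(out, out + 6);
}

// ---------------------------------------------------------------------
// Batched XC integration: energy, Kohn-Sham matrix contributions and
// (optionally) the nuclear gradient contribution.
// Da, Db: per-spin density matrices (Da == Db for closed shells).
// ---------------------------------------------------------------------
// [[Rcpp::export(name = ".cpp_xc_int")]]
List xc_int(List basis, arma::mat Da, arma::mat Db, arma::mat pts,
            arma::vec w, NumericVector coef, bool do_vxc, bool do_grad,
            int natom) {
  std::vector<Shell> sh = shells_from_R(basis);
  int nbf = nbf_total(sh);
  double Exc = 0.0, nelec = 0.0;
  arma::mat Va, Vb, grad;
  if (do_vxc) { Va.zeros(nbf, nbf); Vb.zeros(nbf, nbf); }
  if (do_grad) grad.zeros(natom, 3);
  int np = pts.n_rows;
  const bool closed = arma::approx_equal(Da, Db, "absdiff", 0.0);
  const int BS = 512;
  BasisBatch bb;
  // atom index per basis function
  std::vector<int> bfatom(nbf);
  for (auto& s : sh)
    for (int c = 0; c < ncart(s.l); ++c) bfatom[s.offset + c] = s.atom;
  for (int p0 = 0; p0 < np; p0 += BS) {
    int p1 = std::min(np, p0 + BS);
    arma::mat bpts = pts.rows(p0, p1 - 1);
    arma::vec bw = w.subvec(p0, p1 - 1);
    std::vector<int> act = active_shells(sh, bpts);
    if (act.empty()) continue;
    eval_basis_batch(sh, act, bpts, do_grad ? 2 : 1, bb);
    int nc = bb.colmap.size();
    arma::uvec cols(bb.colmap.data(), nc, false);
    arma::mat Das = Da.submat(cols, cols), Dbs = Db.submat(cols, cols);
    int nb = p1 - p0;
    arma::mat za = bb.phi * Das;
    arma::mat zb = closed ? za : bb.phi * Dbs;
    arma::vec ra_v = arma::sum(za % bb.phi, 1);
    arma::vec rb_v = closed ? ra_v : arma::sum(zb % bb.phi, 1);
    arma::mat gra(nb, 3), grb(nb, 3);
    for (int d = 0; d < 3; ++d) {
      gra.col(d) = 2.0 * arma::sum(za % bb.dphi[d], 1);
      if (closed) grb.col(d) = gra.col(d);
      else grb.col(d) = 2.0 * arma::sum(zb % bb.dphi[d], 1);
    }
    arma::vec fra(nb), frb(nb), fgaa(nb), fgab(nb), fgbb(nb);
    double out[6];
    for (int i = 0; i < nb; ++i) {
      double ra = ra_v(i), rb = rb_v(i);
      double rt = ra + rb;
      nelec += bw(i) * rt;
      if (rt < 1e-11) { fra(i)=frb(i)=fgaa(i)=fgab(i)=fgbb(i)=0; continue; }
      double gaa = arma::dot(gra.row(i), gra.row(i));
      double gab = arma::dot(gra.row(i), grb.row(i));
      double gbb = arma::dot(grb.row(i), grb.row(i));
      xc_point(ra, rb, gaa, gab, gbb, coef[0], coef[1], coef[2], coef[3], out);
      Exc += bw(i) * out[0];
      fra(i) = out[1]; frb(i) = out[2];
      fgaa(i) = out[3]; fgab(i) = out[4]; fgbb(i) = out[5];
    }
    // effective gradient vectors  t_sigma = w (2 fgss grad_rs + fgab grad_rs')
    arma::mat ta(nb, 3), tb(nb, 3);
    for (int i = 0; i < nb; ++i)
      for (int d = 0; d < 3; ++d) {
        ta(i, d) = bw(i) * (2.0 * fgaa(i) * gra(i, d) + fgab(i) * grb(i, d));
        tb(i, d) = bw(i) * (2.0 * fgbb(i) * grb(i, d) + fgab(i) * gra(i, d));
      }
    if (do_vxc) {
      arma::vec wa = bw % fra;
      arma::mat Pa = bb.phi.each_col() % wa;
      arma::mat Qa(nb, nc, arma::fill::zeros);
      for (int d = 0; d < 3; ++d)
        Qa += bb.dphi[d].each_col() % ta.col(d);
      arma::mat Vas = bb.phi.t() * (Pa + Qa) + Qa.t() * bb.phi;
      Va.submat(cols, cols) += 0.5 * (Vas + Vas.t());
      if (!closed) {
        arma::vec wb = bw % frb;
        arma::mat Pb = bb.phi.each_col() % wb;
        arma::mat Qb(nb, nc, arma::fill::zeros);
        for (int d = 0; d < 3; ++d)
          Qb += bb.dphi[d].each_col() % tb.col(d);
        arma::mat Vbs = bb.phi.t() * (Pb + Qb) + Qb.t() * bb.phi;
        Vb.submat(cols, cols) += 0.5 * (Vbs + Vbs.t());
      }
    }
    if (do_grad) {
      arma::vec sa = bw % fra;
      // y_sigma_sum(p, mu) = sum_d t_d(p) dphi_d(p, mu) * D  (ket side)
      arma::mat ya(nb, nc, arma::fill::zeros), yb;
      for (int d = 0; d < 3; ++d) {
        arma::mat tmp_a = bb.dphi[d] * Das;
        ya += tmp_a.each_col() % ta.col(d);
      }
      if (!closed) {
        yb.zeros(nb, nc);
        for (int d = 0; d < 3; ++d) {
          arma::mat tmp_b = bb.dphi[d] * Dbs;
          yb += tmp_b.each_col() % tb.col(d);
        }
      }
      static const int d2map[3][3] = {{0,1,2},{1,3,4},{2,4,5}};
      for (int x = 0; x < 3; ++x) {
        arma::vec g1a = (bb.dphi[x] % za).t() * sa;
        arma::vec g2a(nc, arma::fill::zeros);
        for (int d = 0; d < 3; ++d)
          g2a += (bb.d2phi[d2map[x][d]] % za).t() * ta.col(d);
        arma::vec g3a = arma::sum(bb.dphi[x] % ya, 0).t();
        arma::vec gb(nc, arma::fill::zeros);
        if (closed) {
          gb = g1a + g2a + g3a;
        } else {
          arma::vec sb = bw % frb;
          gb = (bb.dphi[x] % zb).t() * sb;
          for (int d = 0; d < 3; ++d)
            gb += (bb.d2phi[d2map[x][d]] % zb).t() * tb.col(d);
          gb += arma::sum(bb.dphi[x] % yb, 0).t();
        }
        for (int c = 0; c < nc; ++c) {
          int at = bfatom[bb.colmap[c]];
          grad(at, x) -= 2.0 * (g1a(c) + g2a(c) + g3a(c) + gb(c));
        }
      }
    }
  }
  if (do_vxc && closed) Vb = Va;
  List out = List::create(_["Exc"] = Exc, _["nelec"] = nelec);
  if (do_vxc) { out["Va"] = Va; out["Vb"] = Vb; }
  if (do_grad) out["grad"] = grad;
  return out;
}
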