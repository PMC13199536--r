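// TET10 finite-element kernel for structured (affine) tetrahedral meshes
// with J2 (von Mises) plasticity and linear isotropic hardening.
//
// The mesh is a structured decomposition of equal cubes into 6 tetrahedra,
// so every element of a given "type" (position in the 6-tet split) shares
// the same affine Jacobian: the strain-displacement matrices B at the four
// Gauss points are precomputed once per type in R and passed in.
//
// Voigt convention: strain [exx eyy ezz gxy gyz gzx] (engineering shears),
// stress [sxx syy szz txy tyz tzx]. Plastic strain is stored with tensor
// shear components.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void radial_return(const double eps[6], const double ep_in[6],
                                 double alpha_in, double Emod, double nu,
                                 double sy, double H,
                                 double sig[6], double ep_out[6],
                                 double* alpha_out, double* dgamma,
                                 double Dmat[36], bool want_tangent) {
  const double mu = Emod / (2.0 * (1.0 + nu));
  const double kappa = Emod / (3.0 * (1.0 - 2.0 * nu));
  // tensor strain components
  double et[6] = {eps[0], eps[1], eps[2], 0.5 * eps[3], 0.5 * eps[4], 0.5 * eps[5]};
  double evol = et[0] + et[1] + et[2];
  double ed[6] = {et[0] - evol / 3.0, et[1] - evol / 3.0, et[2] - evol / 3.0,
                  et[3], et[4], et[5]};
  double str[6];
  for (int i = 0; i < 6; ++i) str[i] = 2.0 * mu * (ed[i] - ep_in[i]);
  double ss = str[0]*str[0] + str[1]*str[1] + str[2]*str[2]
            + 2.0 * (str[3]*str[3] + str[4]*str[4] + str[5]*str[5]);
  double qtr = std::sqrt(1.5 * ss);
  double ycur = sy + H * alpha_in;
  double dg = 0.0, theta = 1.0, thetabar = 0.0;
  double s[6];
  if (qtr <= ycur || sy == R_PosInf) {
    for (int i = 0; i < 6; ++i) { s[i] = str[i]; ep_out[i] = ep_in[i]; }
    *alpha_out = alpha_in;
  } else {
    dg = (qtr - ycur) / (3.0 * mu + H);
    theta = 1.0 - 3.0 * mu * dg / qtr;
    thetabar = 3.0 * mu / (3.0 * mu + H) - (1.0 - theta);
    for (int i = 0; i < 6; ++i) {
      s[i] = theta * str[i];
      ep_out[i] = ep_in[i] + dg * 1.5 * str[i] / qtr;
    }
    *alpha_out = alpha_in + dg;
  }
  *dgamma = dg;
  sig[0] = kappa * evol + s[0];
  sig[1] = kappa * evol + s[1];
  sig[2] = kappa * evol + s[2];
  sig[3] = s[3]; sig[4] = s[4]; sig[5] = s[5];

  if (!want_tangent) return;
  // D = kappa m m' + 2 mu theta Idev_eng - 2 mu thetabar n n'
  double nrm = std::sqrt(ss);
  double nv[6] = {0, 0, 0, 0, 0, 0};
  if (dg > 0.0 && nrm > 0.0)
    for (int i = 0; i < 6; ++i) nv[i] = str[i] / nrm;
  for (int i = 0; i < 36; ++i) Dmat[i] = 0.0;
  const double third = 1.0 / 3.0;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      Dmat[i * 6 + j] += kappa - 2.0 * mu * theta * third;
  for (int i = 0; i < 3; ++i) Dmat[i * 6 + i] += 2.0 * mu * theta;
  for (int i = 3; i < 6; ++i) Dmat[i * 6 + i] += mu * theta;
  if (dg > 0.0)
    for (int i = 0; i < 6; ++i)
      for (int j = 0; j < 6; ++j)
        Dmat[i * 6 + j] -= 2.0 * mu * thetabar * nv[i] * nv[j];
}

// Point-level access to the stress update (testing hook).
// [[Rcpp::export]]
List j2_point_cpp(NumericVector eps, NumericVector ep_in, double alpha_in,
                  double Emod, double nu, double sy, double H) {
  double sig[6], epo[6], Dmat[36], alpha_o, dg;
  double e[6], epi[6];
  for (int i = 0; i < 6; ++i) { e[i] = eps[i]; epi[i] = ep_in[i]; }
  radial_return(e, epi, alpha_in, Emod, nu, sy, H, sig, epo, &alpha_o, &dg,
                Dmat, true);
  NumericMatrix D(6, 6);
  for (int i = 0; i < 6; ++i)
    for (int j = 0; j < 6; ++j) D(i, j) = Dmat[i * 6 + j];
  return List::create(_["stress"] = NumericVector(sig, sig + 6),
                      _["ep"] = NumericVector(epo, epo + 6),
                      _["alpha"] = alpha_o, _["dgamma"] = dg,
                      _["tangent"] = D);
}

// [[Rcpp::export]]
List fe_assemble_cpp(const arma::imat& conn,        // E x 10, 1-based
                     const arma::ivec& etype,       // E, 1..6
                     const arma::cube& Bg,          // 6 x 30 x (4*6): gauss-major per type
                     double wg,                     // gauss weight * detJ (V/4)
                     const arma::vec& Emod, const arma::vec& sy,
                     const arma::vec& Hmod, double nu,
                     const arma::vec& u,            // 3N
                     const arma::mat& ep_in,        // (E*4) x 6
                     const arma::vec& alpha_in,     // E*4
                     bool want_tangent) {
  const int E = conn.n_rows;
  const int N3 = u.n_elem;
  arma::vec fint(N3, arma::fill::zeros);
  arma::mat ep_out(E * 4, 6);
  arma::vec alpha_out(E * 4);
  int n_yield = 0;
  double dissipation = 0.0;

  std::vector<int> Ti, Tj;
  std::vector<double> Tx;
  if (want_tangent) {
    Ti.reserve((size_t)E * 900);
    Tj.reserve((size_t)E * 900);
    Tx.reserve((size_t)E * 900);
  }

  arma::vec ue(30), fe(30);
  arma::mat Ke(30, 30);
  double Dmat[36], sig[6], epo[6], eps[6], alpha_o, dg;
  arma::mat Dm(6, 6);

  for (int e = 0; e < E; ++e) {
    int t = etype[e] - 1;
    int dof[30];
    for (int a = 0; a < 10; ++a) {
      int nd = conn(e, a) - 1;
      for (int c = 0; c < 3; ++c) {
        dof[3 * a + c] = 3 * nd + c;
        ue[3 * a + c] = u[3 * nd + c];
      }
    }
    fe.zeros();
    if (want_tangent) Ke.zeros();
    for (int g = 0; g < 4; ++g) {
      const arma::mat& B = Bg.slice(t * 4 + g);
      arma::vec ev = B * ue;
      for (int i = 0; i < 6; ++i) eps[i] = ev[i];
      int gp = e * 4 + g;
      double epi[6];
      for (int i = 0; i < 6; ++i) epi[i] = ep_in(gp, i);
      radial_return(eps, epi, alpha_in[gp], Emod[e], nu, sy[e], Hmod[e],
                    sig, epo, &alpha_o, &dg, Dmat, want_tangent);
      for (int i = 0; i < 6; ++i) ep_out(gp, i) = epo[i];
      alpha_out[gp] = alpha_o;
      if (dg > 0.0) {
        ++n_yield;
        double dd = 0.0;
        for (int i = 0; i < 3; ++i) dd += sig[i] * (epo[i] - epi[i]);
        for (int i = 3; i < 6; ++i) dd += 2.0 * sig[i] * (epo[i] - epi[i]);
        dissipation += wg * dd;
      }
      arma::vec sv(6);
      for (int i = 0; i < 6; ++i) sv[i] = sig[i];
      fe += wg * (B.t() * sv);
      if (want_tangent) {
        for (int i = 0; i < 6; ++i)
          for (int j = 0; j < 6; ++j) Dm(i, j) = Dmat[i * 6 + j];
        Ke += wg * (B.t() * Dm * B);
      }
    }
    for (int a = 0; a < 30; ++a) fint[dof[a]] += fe[a];
    if (want_tangent) {
      // lower triangle only (global dof row >= col); K is symmetric
      for (int a = 0; a < 30; ++a)
        for (int b = 0; b < 30; ++b) {
          if (dof[a] < dof[b]) continue;
          Ti.push_back(dof[a] + 1);
          Tj.push_back(dof[b] + 1);
          Tx.push_back(Ke(a, b));
        }
    }
  }

  List out = List::create(
    _["fint"] = fint,
    _["ep"] = ep_out,
    _["alpha"] = alpha_out,
    _["n_yield"] = n_yield,
    _["dissipation"] = dissipation);
  if (want_tangent) {
    out["Ki"] = IntegerVector(Ti.begin(), Ti.end());
    out["Kj"] = IntegerVector(Tj.begin(), Tj.end());
    out["Kx"] = NumericVector(Tx.begin(), Tx.end());
  }
  return out;
}

// Strain tensors at element nodes (B evaluated at nodal natural coords),
// averaged over the elements sharing each node (all elements have equal
// volume on the structured mesh). Returns N x 6 engineering-Voigt strains.
// [[Rcpp::export]]
NumericMatrix fe_nodal_strains_cpp(const arma::imat& conn,
                                   const arma::ivec& etype,
                                   const arma::cube& Bn, // 6 x 30 x (10*6)
                                   const arma::vec& u, int nnode) {
  const int E = conn.n_rows;
  arma::mat acc(nnode, 6, arma::fill::zeros);
  arma::vec cnt(nnode, arma::fill::zeros);
  arma::vec ue(30);
  for (int e = 0; e < E; ++e) {
    int t = etype[e] - 1;
    for (int a = 0; a < 10; ++a) {
      int nd = conn(e, a) - 1;
      for (int c = 0; c < 3; ++c) ue[3 * a + c] = u[3 * nd + c];
    }
    for (int a = 0; a < 10; ++a) {
      const arma::mat& B = Bn.slice(t * 10 + a);
      arma::vec ev = B * ue;
      int nd = conn(e, a) - 1;
      for (int i = 0; i < 6; ++i) acc(nd, i) += ev[i];
      cnt[nd] += 1.0;
    }
  }
  NumericMatrix out(nnode, 6);
  for (int n = 0; n < nnode; ++n)
    for (int i = 0; i < 6; ++i)
      out(n, i) = cnt[n] > 0 ? acc(n, i) / cnt[n] : 0.0;
  return out;
}
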