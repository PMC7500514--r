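// Gibbs sampler for the bivariate latent growth model.
//
// Observation model, subject i, occasion j (binned time c_ij):
//   y^A_ij = x_ij' betaA + u0A_i + u1A_i * c_ij + e^A_ij
//   y^B_ij = x_ij' betaB + u0B_i + u1B_i * c_ij + e^B_ij
//   (e^A, e^B)' ~ N(0, Theta)               2x2, shared across occasions
//   b_i = (u0A, u1A, u0B, u1B)' ~ N(0, Psi)  4x4
//
// Priors: beta ~ N(0, 1e10 I); Psi ~ IW(S0, nu0); Theta ~ IW(T0, m0).
// The improper Mplus-style default corresponds to S0 = 0, nu0 = -p-1,
// which enters the conjugate updates only through the posterior degrees of
// freedom (n - p - 1) and the scatter matrix.
//
// The fixed effects are drawn COLLAPSED: from p(beta | y, Psi, Theta) with
// the random effects integrated out (per-subject marginal covariance
// V_i = Zt_i Psi Zt_i' + Theta (x) I), then b_i | beta conjugately. The
// blocked draw removes the near-confounding of the fixed intercepts with
// the mean of the large random intercepts, which cripples mixing in the
// naive one-at-a-time scheme.
//
// All randomness goes through R's RNG so set.seed() on the R side gives
// full determinism.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat rwishart_bartlett(int nu, const arma::mat& cholS) {
  // W ~ Wishart(nu, S) with cholS = chol(S, "lower"); Bartlett decomposition
  const int p = cholS.n_rows;
  arma::mat A(p, p, arma::fill::zeros);
  for (int i = 0; i < p; ++i) {
    A(i, i) = std::sqrt(R::rchisq(nu - i));
    for (int j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  arma::mat LA = cholS * A;
  return LA * LA.t();
}

static arma::mat rinvwishart(double nu, const arma::mat& S, bool& ok) {
  // Psi ~ IW(S, nu)  <=>  Psi^{-1} ~ Wishart(nu, S^{-1})
  const int p = S.n_rows;
  arma::mat Sinv;
  ok = arma::inv_sympd(Sinv, S);
  if (!ok) return arma::eye(p, p);
  arma::mat L;
  ok = arma::chol(L, Sinv, "lower");
  if (!ok) return arma::eye(p, p);
  arma::mat W = rwishart_bartlett((int) std::lround(nu), L);
  arma::mat out;
  ok = arma::inv_sympd(out, W);
  if (!ok || !out.is_finite()) { ok = false; return arma::eye(p, p); }
  return out;
}

static arma::vec rmvnorm_prec(const arma::vec& rhs, const arma::mat& prec,
                              bool& ok) {
  // draw from N(prec^{-1} rhs, prec^{-1}) via Cholesky of the precision
  const int p = prec.n_rows;
  arma::mat L;
  ok = arma::chol(L, prec, "lower");
  if (!ok) return arma::zeros(p);
  arma::vec mu = arma::solve(arma::trimatl(L), rhs);
  mu = arma::solve(arma::trimatu(L.t()), mu);
  arma::vec z(p);
  for (int i = 0; i < p; ++i) z(i) = R::norm_rand();
  return mu + arma::solve(arma::trimatu(L.t()), z);
}

// [[Rcpp::export]]
List gibbs_bivariate_chain(const arma::mat& X,      // N x q fixed design
                           const arma::vec& ctime,  // N binned times
                           const arma::vec& yA, const arma::vec& yB,
                           const arma::ivec& subj,  // N, 0-based
                           const int nsub,
                           const int n_iter, const int n_burn,
                           const int thin_pv,
                           const bool proper_prior, const double prior_eps,
                           const arma::vec& betaA_init,
                           const arma::vec& betaB_init,
                           const arma::mat& psi_init,
                           const arma::mat& theta_init,
                           const bool sample_psi, const bool sample_theta) {
  const int N = X.n_rows;
  const int q = X.n_cols;

  arma::vec betaA = betaA_init, betaB = betaB_init;
  arma::mat Psi = psi_init, Theta = theta_init;
  arma::mat b(nsub, 4, arma::fill::zeros);

  // per-subject caches: design rows, growth loadings, responses
  std::vector<arma::mat> Xi(nsub), Zi(nsub);
  std::vector<arma::vec> yAi(nsub), yBi(nsub);
  {
    std::vector<std::vector<int> > idx(nsub);
    for (int n = 0; n < N; ++n) idx[subj(n)].push_back(n);
    for (int i = 0; i < nsub; ++i) {
      const int ni = (int) idx[i].size();
      Xi[i].set_size(ni, q);
      Zi[i].set_size(ni, 2);
      yAi[i].set_size(ni);
      yBi[i].set_size(ni);
      for (int k = 0; k < ni; ++k) {
        const int n = idx[i][k];
        Xi[i].row(k) = X.row(n);
        Zi[i](k, 0) = 1.0;
        Zi[i](k, 1) = ctime(n);
        yAi[i](k) = yA(n);
        yBi[i](k) = yB(n);
      }
    }
  }

  const double lambda0 = 1e-10;  // N(0, 1e10) prior precision on beta
  const int n_keep = n_iter - n_burn;
  const int n_pv = (n_keep + thin_pv - 1) / thin_pv;
  arma::mat keep_betaA(n_keep, q), keep_betaB(n_keep, q);
  arma::mat keep_psi(n_keep, 10), keep_theta(n_keep, 3);
  arma::cube keep_pv(nsub, 4, n_pv);

  // IW prior bookkeeping: posterior df = nu0 + n, scale = S0 + scatter,
  // with nu0 = -p-1 (improper flat) or p+1 (weak proper)
  const double nu0_psi = proper_prior ? 5.0 : -5.0;
  const double nu0_theta = proper_prior ? 3.0 : -3.0;
  const double s0 = proper_prior ? prior_eps : 0.0;

  bool ok = true;
  int fail_iter = -1;
  int pv_slot = 0;

  for (int it = 0; it < n_iter; ++it) {
    // (1) collapsed fixed effects: beta | y, Psi, Theta
    arma::mat A(2 * q, 2 * q, arma::fill::zeros);
    arma::vec rhs(2 * q, arma::fill::zeros);
    for (int i = 0; i < nsub; ++i) {
      const int ni = Xi[i].n_rows;
      arma::mat ZPsiZ(2 * ni, 2 * ni);
      // Zt = blkdiag(Zi, Zi) against Psi blocks (A first, B second)
      const arma::mat& Z = Zi[i];
      ZPsiZ.submat(0, 0, ni - 1, ni - 1) =
        Z * Psi.submat(0, 0, 1, 1) * Z.t();
      ZPsiZ.submat(0, ni, ni - 1, 2 * ni - 1) =
        Z * Psi.submat(0, 2, 1, 3) * Z.t();
      ZPsiZ.submat(ni, 0, 2 * ni - 1, ni - 1) =
        ZPsiZ.submat(0, ni, ni - 1, 2 * ni - 1).t();
      ZPsiZ.submat(ni, ni, 2 * ni - 1, 2 * ni - 1) =
        Z * Psi.submat(2, 2, 3, 3) * Z.t();
      for (int k = 0; k < ni; ++k) {
        ZPsiZ(k, k) += Theta(0, 0);
        ZPsiZ(k, ni + k) += Theta(0, 1);
        ZPsiZ(ni + k, k) += Theta(0, 1);
        ZPsiZ(ni + k, ni + k) += Theta(1, 1);
      }
      arma::mat W;
      ok = arma::inv_sympd(W, ZPsiZ);
      if (!ok) { fail_iter = it; break; }
      const arma::mat WAA = W.submat(0, 0, ni - 1, ni - 1);
      const arma::mat WAB = W.submat(0, ni, ni - 1, 2 * ni - 1);
      const arma::mat WBB = W.submat(ni, ni, 2 * ni - 1, 2 * ni - 1);
      const arma::mat& Xs = Xi[i];
      A.submat(0, 0, q - 1, q - 1) += Xs.t() * WAA * Xs;
      A.submat(0, q, q - 1, 2 * q - 1) += Xs.t() * WAB * Xs;
      A.submat(q, q, 2 * q - 1, 2 * q - 1) += Xs.t() * WBB * Xs;
      rhs.head(q) += Xs.t() * (WAA * yAi[i] + WAB * yBi[i]);
      rhs.tail(q) += Xs.t() * (WAB.t() * yAi[i] + WBB * yBi[i]);
    }
    if (!ok) break;
    A.submat(q, 0, 2 * q - 1, q - 1) =
      A.submat(0, q, q - 1, 2 * q - 1).t();
    A.diag() += lambda0;
    arma::vec beta = rmvnorm_prec(rhs, A, ok);
    if (!ok) { fail_iter = it; break; }
    betaA = beta.head(q);
    betaB = beta.tail(q);

    // (2) subject random effects | beta, Psi, Theta
    arma::mat Thinv, Psiinv;
    ok = arma::inv_sympd(Thinv, Theta) && arma::inv_sympd(Psiinv, Psi);
    if (!ok) { fail_iter = it; break; }
    const double a = Thinv(0, 0), c12 = Thinv(0, 1), d = Thinv(1, 1);
    for (int i = 0; i < nsub; ++i) {
      const arma::vec rA = yAi[i] - Xi[i] * betaA;
      const arma::vec rB = yBi[i] - Xi[i] * betaB;
      const arma::mat ZtZ = Zi[i].t() * Zi[i];
      arma::mat prec = Psiinv;
      prec.submat(0, 0, 1, 1) += a * ZtZ;
      prec.submat(0, 2, 1, 3) += c12 * ZtZ;
      prec.submat(2, 0, 3, 1) += c12 * ZtZ;
      prec.submat(2, 2, 3, 3) += d * ZtZ;
      const arma::vec ZrA = Zi[i].t() * rA;
      const arma::vec ZrB = Zi[i].t() * rB;
      arma::vec rhs_b(4);
      rhs_b(0) = a * ZrA(0) + c12 * ZrB(0);
      rhs_b(1) = a * ZrA(1) + c12 * ZrB(1);
      rhs_b(2) = c12 * ZrA(0) + d * ZrB(0);
      rhs_b(3) = c12 * ZrA(1) + d * ZrB(1);
      const arma::vec bi = rmvnorm_prec(rhs_b, prec, ok);
      if (!ok) { fail_iter = it; break; }
      b.row(i) = bi.t();
    }
    if (!ok) break;

    // (3) random-effect covariance | b
    if (sample_psi) {
      arma::mat Sb = b.t() * b;
      Sb.diag() += s0;
      const double nu_n = nu0_psi + nsub;
      if (nu_n <= 3.0) { ok = false; fail_iter = it; break; }
      Psi = rinvwishart(nu_n, Sb, ok);
      if (!ok) { fail_iter = it; break; }
    }

    // (4) residual covariance | beta, b
    if (sample_theta) {
      double sAA = 0, sAB = 0, sBB = 0;
      for (int i = 0; i < nsub; ++i) {
        const arma::vec eA = yAi[i] - Xi[i] * betaA -
          Zi[i] * b.row(i).cols(0, 1).t();
        const arma::vec eB = yBi[i] - Xi[i] * betaB -
          Zi[i] * b.row(i).cols(2, 3).t();
        sAA += arma::dot(eA, eA);
        sAB += arma::dot(eA, eB);
        sBB += arma::dot(eB, eB);
      }
      arma::mat Se = { {sAA + s0, sAB}, {sAB, sBB + s0} };
      const double m_n = nu0_theta + N;
      if (m_n <= 1.0) { ok = false; fail_iter = it; break; }
      Theta = rinvwishart(m_n, Se, ok);
      if (!ok) { fail_iter = it; break; }
    }

    if (it >= n_burn) {
      const int k = it - n_burn;
      keep_betaA.row(k) = betaA.t();
      keep_betaB.row(k) = betaB.t();
      arma::rowvec psirow(10), throw_(3);
      int pos = 0;
      for (int r = 0; r < 4; ++r)
        for (int cc = r; cc < 4; ++cc) psirow(pos++) = Psi(r, cc);
      throw_(0) = Theta(0, 0); throw_(1) = Theta(0, 1);
      throw_(2) = Theta(1, 1);
      keep_psi.row(k) = psirow;
      keep_theta.row(k) = throw_;
      if (k % thin_pv == 0) {
        keep_pv.slice(pv_slot) = b;
        ++pv_slot;
      }
    }
  }

  return List::create(
    _["ok"] = ok, _["fail_iter"] = fail_iter,
    _["betaA"] = keep_betaA, _["betaB"] = keep_betaB,
    _["psi"] = keep_psi, _["theta"] = keep_theta,
    _["pv"] = keep_pv, _["n_pv"] = pv_slot);
}
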