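// Pairwise Gaussian MMI-PhiID over all region pairs of one subject.
// The R level supplies the joint covariance of the stacked (past, present)
// region blocks and the Moebius coefficients of the syn->syn atom; this
// kernel evaluates, per pair, the nine Gaussian mutual informations and the
// seven MMI redundancies that make up the 16 cumulative lattice values.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

static inline double logdet_sub(const arma::mat& S, const arma::uvec& idx) {
  double val, sign;
  arma::log_det(val, sign, S.submat(idx, idx));
  if (sign <= 0) Rcpp::stop("covariance submatrix is not positive definite");
  return val;
}

static double gmi(const arma::mat& S, const arma::uvec& a, const arma::uvec& b) {
  arma::uvec ab = arma::join_cols(a, b);
  return 0.5 * (logdet_sub(S, a) + logdet_sub(S, b) - logdet_sub(S, ab)) /
         std::log(2.0);
}

// [[Rcpp::export]]
arma::mat phid_syn_pairs_cpp(const arma::mat& Sbig, const int n,
                             const double ridge,
                             const arma::vec& mobius_syn) {
  if ((int)Sbig.n_rows != 2 * n || (int)Sbig.n_cols != 2 * n)
    Rcpp::stop("Sbig must be 2n x 2n");
  if (mobius_syn.n_elem != 16) Rcpp::stop("mobius_syn must have 16 entries");
  const arma::uvec s1 = {0}, s2 = {1}, s12 = {0, 1};
  const arma::uvec t1 = {2}, t2 = {3}, t12 = {2, 3};
  arma::mat out(n, n, arma::fill::zeros);
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      arma::uvec idx = {(arma::uword)i, (arma::uword)j,
                        (arma::uword)(n + i), (arma::uword)(n + j)};
      arma::mat S = Sbig.submat(idx, idx);
      S.diag() += ridge;
      const double m11 = gmi(S, s1, t1), m12 = gmi(S, s1, t2);
      const double m21 = gmi(S, s2, t1), m22 = gmi(S, s2, t2);
      const double m1J = gmi(S, s1, t12), m2J = gmi(S, s2, t12);
      const double mJ1 = gmi(S, s12, t1), mJ2 = gmi(S, s12, t2);
      const double mJJ = gmi(S, s12, t12);
      // Cumulative values, indexed 4*source + target with
      // 0 = red, 1 = un1, 2 = un2, 3 = syn (matches phiid_lattice()).
      double icap[16];
      icap[4 * 1 + 1] = m11; icap[4 * 1 + 2] = m12; icap[4 * 1 + 3] = m1J;
      icap[4 * 2 + 1] = m21; icap[4 * 2 + 2] = m22; icap[4 * 2 + 3] = m2J;
      icap[4 * 3 + 1] = mJ1; icap[4 * 3 + 2] = mJ2; icap[4 * 3 + 3] = mJJ;
      icap[4 * 0 + 1] = std::min(m11, m21);
      icap[4 * 0 + 2] = std::min(m12, m22);
      icap[4 * 0 + 3] = std::min(m1J, m2J);
      icap[4 * 1 + 0] = std::min(m11, m12);
      icap[4 * 2 + 0] = std::min(m21, m22);
      icap[4 * 3 + 0] = std::min(mJ1, mJ2);
      icap[4 * 0 + 0] = std::min(std::min(m11, m12), std::min(m21, m22));
      double syn = 0.0;
      for (int k = 0; k < 16; ++k) syn += mobius_syn[k] * icap[k];
      out(i, j) = out(j, i) = syn;
    }
  }
  return out;
}
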