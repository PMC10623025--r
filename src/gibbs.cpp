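// Single-site Gibbs sampler for the (multi-trait) animal model.
//
// Location effects (fixed effects, then breeding values animal by animal)
// are sampled from their scalar normal full conditionals given the current
// G0 and R0 (Gauss-Seidel sweep over the mixed-model equations); G0 and R0
// are then refreshed from their inverse-Wishart full conditionals. All
// randomness comes from R's RNG so set.seed() makes chains bit-identical.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Inverse-Wishart draw via the Bartlett decomposition on R's RNG.
// scale must be symmetric PD, dof > t - 1.
static arma::mat riwish_bartlett(const arma::mat& scale, double dof) {
  const int t = scale.n_rows;
  arma::mat U;
  if (!arma::chol(U, scale))
    stop("inverse-Wishart scale matrix is not positive definite");
  arma::mat B = arma::inv(arma::trimatu(U)); // B B' = scale^{-1}
  arma::mat A(t, t, arma::fill::zeros);
  for (int i = 0; i < t; ++i) {
    A(i, i) = std::sqrt(R::rchisq(dof - i));
    for (int j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  arma::mat T = B * A;
  arma::mat W = T * T.t(); // ~ Wishart(dof, scale^{-1})
  return arma::inv_sympd(W);
}

// [[Rcpp::export]]
List gibbs_chain_cpp(const arma::mat& y, const List& Xlist,
                     const arma::uvec& animal, const arma::sp_mat& Ainv,
                     arma::mat G0, arma::mat R0,
                     const arma::mat& Sg, double nug,
                     const arma::mat& Sr, double nur,
                     int total, int burnin, int thin,
                     bool fix_var, double overflow_mult) {
  const int n = y.n_rows, t = y.n_cols, q = Ainv.n_rows;
  if ((int)animal.n_elem != n) stop("animal index length mismatch");
  if ((int)Xlist.size() != t) stop("one design matrix per trait required");

  std::vector<arma::mat> X(t);
  std::vector<arma::vec> xtx(t);
  for (int k = 0; k < t; ++k) {
    X[k] = as<arma::mat>(Xlist[k]);
    if ((int)X[k].n_rows != n) stop("design rows must match records");
    xtx[k] = arma::sum(arma::square(X[k]), 0).t();
  }

  // record lists per animal (0-based)
  std::vector<std::vector<int> > recs(q);
  for (int i = 0; i < n; ++i) {
    int a = animal(i) - 1;
    if (a < 0 || a >= q) stop("animal code outside pedigree");
    recs[a].push_back(i);
  }
  arma::vec ainv_diag(q);
  for (int a = 0; a < q; ++a) ainv_diag(a) = Ainv(a, a);

  std::vector<arma::vec> beta(t);
  for (int k = 0; k < t; ++k) beta[k].zeros(X[k].n_cols);
  arma::mat u(q, t, arma::fill::zeros);
  arma::mat e = y; // residuals at current locations (all zero)

  const arma::vec g_guard = overflow_mult * G0.diag();
  const arma::vec r_guard = overflow_mult * R0.diag();

  const int n_store = (total - burnin) / thin;
  const int tri = t * (t + 1) / 2;
  arma::mat Gs(n_store > 0 ? n_store : 0, tri);
  arma::mat Rs(n_store > 0 ? n_store : 0, tri);
  arma::ivec store_iter(n_store > 0 ? n_store : 0);
  std::vector<arma::vec> beta_sum(t);
  for (int k = 0; k < t; ++k) beta_sum[k].zeros(X[k].n_cols);
  arma::mat u_sum(q, t, arma::fill::zeros);
  int n_loc = 0, stored = 0;

  for (int iter = 1; iter <= total; ++iter) {
    arma::mat Rinv, Ginv;
    if (!arma::inv_sympd(Rinv, R0))
      stop("residual covariance not positive definite at iteration %d", iter);
    if (!arma::inv_sympd(Ginv, G0))
      stop("genetic covariance not positive definite at iteration %d", iter);

    // fixed effects, trait by trait
    for (int k = 0; k < t; ++k) {
      for (unsigned int j = 0; j < X[k].n_cols; ++j) {
        const double old = beta[k](j);
        e.col(k) += X[k].col(j) * old;
        arma::vec w = e * Rinv.col(k);
        const double num = arma::dot(X[k].col(j), w);
        const double prec = Rinv(k, k) * xtx[k](j);
        const double val = num / prec + R::norm_rand() / std::sqrt(prec);
        beta[k](j) = val;
        e.col(k) -= X[k].col(j) * val;
      }
    }

    // breeding values, animal by animal within trait
    for (int a = 0; a < q; ++a) {
      const std::vector<int>& ra = recs[a];
      for (int k = 0; k < t; ++k) {
        const double old = u(a, k);
        for (size_t m = 0; m < ra.size(); ++m) e(ra[m], k) += old;
        u(a, k) = 0.0;
        // prior cross term from A-inverse row a
        arma::rowvec au(t, arma::fill::zeros);
        for (arma::sp_mat::const_col_iterator it = Ainv.begin_col(a);
             it != Ainv.end_col(a); ++it)
          au += (*it) * u.row(it.row());
        const double s = arma::dot(Ginv.row(k), au);
        double num = 0.0;
        for (size_t m = 0; m < ra.size(); ++m)
          num += arma::dot(Rinv.row(k), e.row(ra[m]));
        const double prec = Rinv(k, k) * (double)ra.size() +
          Ginv(k, k) * ainv_diag(a);
        const double val = (num - s) / prec +
          R::norm_rand() / std::sqrt(prec);
        u(a, k) = val;
        for (size_t m = 0; m < ra.size(); ++m) e(ra[m], k) -= val;
      }
    }

    if (!fix_var) {
      arma::mat AU(q, t);
      AU = arma::mat(Ainv * u);
      G0 = riwish_bartlett(Sg + u.t() * AU, nug + q);
      R0 = riwish_bartlett(Sr + e.t() * e, nur + n);
      if (arma::any(G0.diag() > g_guard) || arma::any(R0.diag() > r_guard))
        stop("divergent chain: sampled variance exceeded the overflow guard "
             "at iteration %d", iter);
    }

    if (iter > burnin) {
      for (int k = 0; k < t; ++k) beta_sum[k] += beta[k];
      u_sum += u;
      ++n_loc;
      if ((iter - burnin) % thin == 0 && stored < n_store) {
        int c = 0;
        for (int r = 0; r < t; ++r)
          for (int cc = 0; cc <= r; ++cc) {
            Gs(stored, c) = G0(r, cc);
            Rs(stored, c) = R0(r, cc);
            ++c;
          }
        store_iter(stored) = iter;
        ++stored;
      }
    }
  }

  List beta_mean(t);
  for (int k = 0; k < t; ++k)
    beta_mean[k] = n_loc > 0 ? arma::vec(beta_sum[k] / n_loc) : beta_sum[k];
  return List::create(
    _["G"] = Gs, _["R"] = Rs, _["iteration"] = store_iter,
    _["beta_mean"] = beta_mean,
    _["u_mean"] = n_loc > 0 ? arma::mat(u_sum / n_loc) : u_sum,
    _["n_stored"] = stored);
}
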