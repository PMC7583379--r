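#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Per-layer linear solves of the first-order Modified Patankar update.
// c_mat:  pools x layers, current amounts (grams)
// agg:    aggregated production rates (unique donor/receiver pairs x layers)
// ui, uj: 1-based receiver/donor pool indices of the aggregated pairs
// d_tot:  total destruction rate per pool per layer (incl. boundary losses)
// src:    donor-free production per pool per layer
// [[Rcpp::export]]
arma::mat emp_solve_layers(const arma::mat& c_mat, const arma::mat& agg,
                           const arma::ivec& ui, const arma::ivec& uj,
                           const arma::mat& d_tot, const arma::mat& src,
                           double dt) {
  const arma::uword np = c_mat.n_rows, nl = c_mat.n_cols, nu = ui.n_elem;
  arma::mat out(np, nl);
  arma::mat a(np, np, arma::fill::zeros);
  for (arma::uword k = 0; k < nl; ++k) {
    arma::vec c0 = c_mat.col(k);
    arma::vec cs = arma::clamp(c0, 1e-300, arma::datum::inf);
    a.zeros();
    for (arma::uword t = 0; t < nu; ++t) {
      a(ui[t] - 1, uj[t] - 1) -= dt * agg(t, k) / cs[uj[t] - 1];
    }
    for (arma::uword i = 0; i < np; ++i) {
      a(i, i) += 1.0 + dt * d_tot(i, k) / cs[i];
    }
    arma::vec rhs = c0 + dt * src.col(k);
    arma::vec sol = arma::solve(a, rhs, arma::solve_opts::fast);
    out.col(k) = arma::clamp(sol, 0.0, arma::datum::inf);
  }
  return out;
}
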