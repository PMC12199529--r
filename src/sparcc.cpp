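#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Iterative SparCC core on a precomputed log-ratio variation matrix.
// First pass uses the no-exclusion closed form; each subsequent pass
// excludes the most strongly correlated remaining pair above `threshold`
// and re-solves the sparsity linear system. Basis variances are floored
// at 1e-8.

static arma::mat rho_from(const arma::vec& omega, const arma::mat& t_mat) {
  const arma::uword D = t_mat.n_rows;
  arma::vec sq = arma::sqrt(omega);
  arma::mat rho = arma::repmat(omega, 1, D);
  rho += rho.t();
  rho -= t_mat;
  rho /= 2.0 * (sq * sq.t());
  rho.clamp(-1.0, 1.0);
  rho.diag().ones();
  return rho;
}

// [[Rcpp::export]]
List sparcc_core_cpp(const arma::mat& t_mat, double threshold,
                     int max_iters) {
  const arma::uword D = t_mat.n_rows;
  arma::vec t_row = arma::sum(t_mat, 1);
  arma::vec omega = (t_row - arma::accu(t_row) / (2.0 * (D - 1))) /
    (double)(D - 2);
  omega.clamp(1e-8, arma::datum::inf);
  arma::mat rho = rho_from(omega, t_mat);

  arma::mat incl(D, D, arma::fill::ones);
  incl.diag().zeros();
  std::vector<int> exc_i, exc_j;

  for (int iter = 0; iter < max_iters; ++iter) {
    arma::mat cand = arma::abs(rho) % incl;
    arma::uword idx = cand.index_max();
    if (cand(idx) <= threshold) break;
    arma::uword i = idx % D, j = idx / D;
    incl(i, j) = 0.0;
    incl(j, i) = 0.0;
    arma::vec m = arma::sum(incl, 1);
    arma::vec om;
    bool solvable = m.min() > 0.0;
    if (solvable) {
      arma::mat M = incl;
      M.diag() = m;
      arma::vec ti = arma::sum(t_mat % incl, 1);
      solvable = arma::solve(om, M, ti, arma::solve_opts::no_approx);
    }
    if (!solvable) {
      // excluding this pair would strand a genus or make the basis
      // system singular; keep the current estimate instead
      incl(i, j) = 1.0;
      incl(j, i) = 1.0;
      break;
    }
    exc_i.push_back((int)std::min(i, j) + 1);
    exc_j.push_back((int)std::max(i, j) + 1);
    om.clamp(1e-8, arma::datum::inf);
    omega = om;
    rho = rho_from(omega, t_mat);
  }

  IntegerMatrix excluded(exc_i.size(), 2);
  for (size_t k = 0; k < exc_i.size(); ++k) {
    excluded(k, 0) = exc_i[k];
    excluded(k, 1) = exc_j[k];
  }
  return List::create(_["rho"] = rho, _["basis_variance"] = omega,
                      _["excluded_pairs"] = excluded);
}
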