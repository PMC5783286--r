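#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Marginal log-likelihood of a panel dataset under a time-homogeneous Markov
// multistate model with censored state sets (forward recursion).
//
// The design list is prepared in R (see panel_design()) and contains a fully
// indexed, flat representation of the data:
//   n_states            number of latent states
//   trans_from/trans_to 0-based state indices per allowed transition
//   lambda_idx          0-based index into theta of each log baseline rate
//   beta_idx/beta_cov   per transition: 0-based theta indices of the
//                       regression coefficients and the matching 0-based
//                       columns of the covariate profile matrix
//   profiles            unique covariate rows (n_profiles x n_covariates)
//   pair_profile/pair_dt unique (profile, interval length) combinations
//   interval_pair       0-based pair index per observation interval
//   masks               one row per visit: non-negative weights over latent
//                       states (initial row = initial-state distribution,
//                       later rows = censored-set indicators)
//   subj_obs_offset     0-based row of each subject's first visit in masks
//   subj_n_obs          visits per subject
//   subj_int_offset     0-based position of each subject's first interval in
//                       interval_pair
//
// Each unique (profile, dt) requires one matrix exponential per evaluation;
// the recursion itself is a chain of small vector-matrix products.

// [[Rcpp::export]]
double panel_loglik_cpp(NumericVector theta, List design) {
  const int ns = as<int>(design["n_states"]);
  IntegerVector tf = design["trans_from"], tt = design["trans_to"];
  IntegerVector li = design["lambda_idx"];
  List bidx = design["beta_idx"], bcov = design["beta_cov"];
  arma::mat profiles = as<arma::mat>(design["profiles"]);
  IntegerVector pair_profile = design["pair_profile"];
  NumericVector pair_dt = design["pair_dt"];
  IntegerVector ipair = design["interval_pair"];
  arma::mat masks = as<arma::mat>(design["masks"]);
  IntegerVector so = design["subj_obs_offset"];
  IntegerVector sl = design["subj_n_obs"];
  IntegerVector si = design["subj_int_offset"];

  const int ntr = tf.size();
  const int nprof = profiles.n_rows;
  const int npair = pair_dt.size();
  const int nsub = so.size();
  const double neg_inf = -std::numeric_limits<double>::infinity();

  // generator matrix per covariate profile
  std::vector<arma::mat> Q(nprof, arma::mat(ns, ns, arma::fill::zeros));
  for (int k = 0; k < nprof; ++k) {
    Q[k].zeros();
    for (int t = 0; t < ntr; ++t) {
      double lp = theta[li[t]];
      IntegerVector bi = bidx[t], bc = bcov[t];
      for (int b = 0; b < bi.size(); ++b)
        lp += theta[bi[b]] * profiles(k, bc[b]);
      Q[k](tf[t], tt[t]) = std::exp(lp);
    }
    for (int r = 0; r < ns; ++r) {
      double rs = arma::accu(Q[k].row(r)) - Q[k](r, r);
      Q[k](r, r) = -rs;
    }
    if (!Q[k].is_finite()) return neg_inf;
  }

  // transition probability matrix per unique (profile, dt)
  std::vector<arma::mat> P(npair);
  for (int m = 0; m < npair; ++m) {
    P[m] = arma::expmat(Q[pair_profile[m]] * pair_dt[m]);
    if (!P[m].is_finite()) return neg_inf;
    // guard against breakdown of the exponential at extreme intensities:
    // a valid result is row-stochastic up to a small numerical slack
    if (P[m].min() < -1e-8 || P[m].max() > 1.0 + 1e-8) return neg_inf;
    arma::vec rs = arma::sum(P[m], 1);
    if (arma::abs(rs - 1.0).max() > 1e-6) return neg_inf;
    // scaling-and-squaring can leave tiny negative entries
    P[m].for_each([](arma::mat::elem_type& v) { if (v < 0) v = 0; });
  }

  double ll = 0.0;
  arma::rowvec alpha(ns);
  for (int i = 0; i < nsub; ++i) {
    const int o0 = so[i], nvis = sl[i], j0 = si[i];
    alpha = masks.row(o0);
    for (int j = 0; j < nvis - 1; ++j) {
      alpha = alpha * P[ipair[j0 + j]];
      alpha %= masks.row(o0 + j + 1);
      double s = arma::accu(alpha);
      if (!(s > 0) || !std::isfinite(s)) return neg_inf;
      ll += std::log(s);
      alpha /= s;
    }
  }
  return ll;
}
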