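#include <Rcpp.h>
using namespace Rcpp;

// Negative log-likelihood of one block's generalized beta regression.
//
// theta = (gamma0_1..gamma0_L, gamma_1..gamma_p, log_beta) with
// alpha_{il} = beta_b * exp(gamma0_l + sum_k gamma_k * Xs(i,k)), so that
// logit(E Z_{il}) = log(alpha_{il}) - log(beta_b) = gamma0_l + Xs_i' gamma.
//
// Data is pre-digested by the R caller, constant across optimizer calls:
//   Xs     n x p covariate matrix (no intercept column; p may be 0)
//   W      n x L matrix of logit(z) = log(z/(1-z))
//   T      n vector of log1p(rowSums(z/(1-z)))
//   rowcon n vector of -rowSums(W) - 2*rowSums(log1p(-z))
//
// Returns +Inf for any non-finite theta or overflowed intermediate, so the
// objective is safe for derivative-free optimizers.
// [[Rcpp::export]]
double gbeta_block_nll(NumericVector theta, NumericMatrix Xs, NumericMatrix W,
                       NumericVector T, NumericVector rowcon) {
  const int n = W.nrow(), L = W.ncol(), p = Xs.ncol();
  if (theta.size() != L + p + 1) stop("theta has wrong length");
  for (int j = 0; j < theta.size(); ++j)
    if (!R_finite(theta[j])) return R_PosInf;

  const double log_beta = theta[L + p];
  if (log_beta > 500.0 || log_beta < -500.0) return R_PosInf;
  const double beta_b = std::exp(log_beta);
  const double lgb = std::lgamma(beta_b);

  std::vector<double> e0(L);  // beta_b * exp(gamma0_l)
  for (int l = 0; l < L; ++l) {
    double g0 = theta[l];
    if (g0 > 500.0 || g0 < -500.0) return R_PosInf;
    e0[l] = beta_b * std::exp(g0);
  }

  double nll = 0.0;
  for (int i = 0; i < n; ++i) {
    double xb = 0.0;
    for (int k = 0; k < p; ++k) xb += theta[L + k] * Xs(i, k);
    if (!R_finite(xb) || xb > 500.0 || xb < -500.0) return R_PosInf;
    const double exb = std::exp(xb);

    double A = 0.0, slg = 0.0, saw = 0.0;
    for (int l = 0; l < L; ++l) {
      const double a = e0[l] * exb;
      if (!R_finite(a) || a <= 0.0) return R_PosInf;
      A += a;
      slg += std::lgamma(a);
      saw += a * W(i, l);
    }
    const double ll_i =
        std::lgamma(A + beta_b) - lgb - slg + saw + rowcon[i] - (A + beta_b) * T[i];
    if (!R_finite(ll_i)) return R_PosInf;
    nll -= ll_i;
  }
  return R_finite(nll) ? nll : R_PosInf;
}
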