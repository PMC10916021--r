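# Closed-form power of the inverse-variance-weighted region statistic under
# compound-symmetric correlation of the per-CpG effect estimates.

#' Standard error of the IVW estimate under compound symmetry
#'
#' For \eqn{\Omega = \sigma_n^2 [(1 - \rho) I + \rho 1 1']} (every pair of
#' the `L` per-CpG effect estimates shares correlation `rho`), the combined
#' inverse-variance-weighted estimate has standard error
#' \deqn{\sqrt{(1'\Omega^{-1}1)^{-1}} = \sigma_n \sqrt{\frac{1 + (L-1)\rho}{L}}.}
#' At `rho = 0` this is the usual \eqn{\sigma_n/\sqrt{L}} of `L` independent
#' estimates; at `rho = 1` it equals `sigma_n`: perfectly correlated CpGs
#' carry one effective observation.
#'
#' @param sigma_n positive per-CpG effect-estimate standard deviation,
#'   \eqn{\sigma / \sqrt{\sum_i (X_i - \bar X)^2}}.
#' @param L block size (number of CpG sites), `>= 1`.
#' @param rho common pairwise correlation; must exceed `-1/(L - 1)` for a
#'   positive-definite `Omega` (`rho = 1` is allowed as the degenerate limit).
#' @return the standard error, a single positive number.
#' @export
compound_symmetry_se <- function(sigma_n, L, rho) {
  if (length(sigma_n) != 1L || !is.finite(sigma_n) || sigma_n <= 0)
    stop("'sigma_n' must be a single positive number")
  if (length(L) != 1L || L < 1 || L != round(L)) stop("'L' must be an integer >= 1")
  if (length(rho) != 1L || !is.finite(rho) || rho > 1)
    stop("'rho' must be a single number <= 1")
  if (L > 1 && rho <= -1 / (L - 1))
    stop("Omega is not positive definite: rho must exceed ", -1 / (L - 1))
  sigma_n * sqrt((1 + (L - 1) * rho) / L)
}

#' Theoretical power of the IVW region statistic
#'
#' Power of the two-sided level-`alpha_level` z-test based on the
#' inverse-variance-weighted combined estimate when the true effect is
#' `gamma1` and the `L` per-CpG effect estimates have common standard
#' deviation `sigma_n` and compound-symmetric correlation `rho`:
#' \deqn{P(Z > -\gamma_1/SE + z_{1-\alpha/2}) +
#'       P(Z < -\gamma_1/SE + z_{\alpha/2}),}
#' with `SE` from [compound_symmetry_se()]. At `gamma1 = 0` the two tails sum
#' exactly to `alpha_level`. For fixed `gamma1 != 0` the power is strictly
#' decreasing in `rho`: stronger correlation among the combined estimates
#' shrinks the effective sample size of the meta-analysis.
#'
#' @param gamma1 true phenotype effect (any real number).
#' @param sigma_n per-CpG effect-estimate standard deviation.
#' @param L block size.
#' @param rho common pairwise correlation (see [compound_symmetry_se()]).
#' @param alpha_level two-sided test level in (0, 1).
#' @return the power, a number in (0, 1).
#' @examples
#' dmrff_power(0.5, sigma_n = 1, L = 2, rho = 0)    # about 0.109
#' dmrff_power(0.5, sigma_n = 1, L = 2, rho = 1)    # about 0.079
#' @export
dmrff_power <- function(gamma1, sigma_n = 1, L = 2L, rho = 0,
                        alpha_level = 0.05) {
  if (length(alpha_level) != 1L || alpha_level <= 0 || alpha_level >= 1)
    stop("'alpha_level' must lie in (0, 1)")
  se <- compound_symmetry_se(sigma_n, L, rho)
  shift <- -gamma1 / se
  pnorm(shift + qnorm(1 - alpha_level / 2), lower.tail = FALSE) +
    pnorm(shift + qnorm(alpha_level / 2))
}
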