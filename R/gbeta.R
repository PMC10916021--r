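#' The generalized beta (Libby--Novick) distribution
#'
#' Density, random generation and mean for the L-variate generalized beta
#' distribution of Libby and Novick. A vector \eqn{Z = (Z_1, \dots, Z_L)}
#' follows this distribution when \eqn{Z_l = P_l / (P_l + Q)} with independent
#' \eqn{P_l \sim \mathrm{Gamma}(\alpha_l, 1)} and a single shared
#' \eqn{Q \sim \mathrm{Gamma}(\beta, 1)}. The shared \eqn{Q} induces positive
#' dependence between coordinates while every marginal stays
#' \eqn{\mathrm{Beta}(\alpha_l, \beta)}; for \eqn{L = 1} the distribution is
#' the ordinary beta distribution. This is the block model for the DNA
#' methylation beta values of a run of correlated CpG sites.
#'
#' The log density is
#' \deqn{\log\Gamma(\textstyle\sum_l \alpha_l + \beta) - \log\Gamma(\beta)
#'   - \sum_l \log\Gamma(\alpha_l)
#'   + \sum_l \left[(\alpha_l - 1)\,\mathrm{logit}(z_l) - 2\log(1 - z_l)\right]
#'   - (\textstyle\sum_l \alpha_l + \beta)\,
#'     \log\left(1 + \sum_l \frac{z_l}{1 - z_l}\right),}
#' evaluated entirely in log space (via `lgamma` and `log1p`) so it stays
#' finite for any `z` strictly inside machine-representable (0, 1).
#'
#' @param z numeric vector of length `L` (one observation) or an `n x L`
#'   matrix (one observation per row). All values must lie strictly in (0, 1);
#'   boundary values are rejected, clipping is the caller's responsibility.
#' @param n number of observations to draw.
#' @param alpha vector of `L` positive shape parameters, one per coordinate.
#' @param beta single positive shared shape parameter.
#' @param log logical; return the log density?
#' @return `dgbeta` returns the (log) density, one value per observation.
#'   `rgbeta` returns an `n x L` matrix of draws in (0, 1); it uses the global
#'   RNG, so call `set.seed()` first for reproducibility. `gbeta_mean` returns
#'   the mean vector `alpha / (alpha + beta)`, whose logit equals
#'   `log(alpha) - log(beta)` exactly.
#' @examples
#' dgbeta(c(0.5, 0.5), alpha = c(1, 1), beta = 1)   # 32/27
#' set.seed(1)
#' z <- rgbeta(1000, alpha = c(3, 3), beta = 3)
#' cor(z[, 1], z[, 2])                              # positive: shared Q
#' gbeta_mean(c(1, 3), 1)                           # 0.5, 0.75
#' @export
dgbeta <- function(z, alpha, beta, log = FALSE) {
  check_gbeta_params(alpha, beta)
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  z <- as.matrix(z)
  if (ncol(z) != length(alpha))
    stop("'z' has ", ncol(z), " columns but 'alpha' has length ", length(alpha))
  if (any(!is.finite(z)) || any(z <= 0) || any(z >= 1))
    stop("all values of 'z' must lie strictly in (0, 1)")

  w <- qlogis(z)                               # log(z / (1 - z))
  lt <- log1p(rowSums(exp(w)))                 # log(1 + sum z/(1-z))
  A <- sum(alpha)
  ll <- lgamma(A + beta) - lgamma(beta) - sum(lgamma(alpha)) +
    drop(w %*% (alpha - 1)) - 2 * rowSums(log1p(-z)) - (A + beta) * lt
  if (log) ll else exp(ll)
}

#' @rdname dgbeta
#' @export
rgbeta <- function(n, alpha, beta) {
  check_gbeta_params(alpha, beta)
  if (length(n) != 1L || !is.finite(n) || n < 1) stop("'n' must be a positive integer")
  n <- as.integer(n)
  L <- length(alpha)
  P <- matrix(rgamma(n * L, shape = rep(alpha, each = n), rate = 1), n, L)
  Q <- rgamma(n, shape = beta, rate = 1)
  P / (P + Q)
}

#' @rdname dgbeta
#' @export
gbeta_mean <- function(alpha, beta) {
  check_gbeta_params(alpha, beta)
  alpha / (alpha + beta)
}

check_gbeta_params <- function(alpha, beta) {
  if (length(alpha) < 1L || any(!is.finite(alpha)) || any(alpha <= 0))
    stop("'alpha' must be a vector of positive finite values")
  if (length(beta) != 1L || !is.finite(beta) || beta <= 0)
    stop("'beta' must be a single positive finite value")
  invisible(TRUE)
}
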