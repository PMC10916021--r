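# Simplified comparison methods: per-CpG EWAS on M-values and the
# inverse-variance-weighted (IVW) region statistic that summarizes EWAS
# effect estimates across a block.

#' Convert between beta values and M-values
#'
#' `beta2m` applies the logit transform on the log2 scale,
#' `M = log2(z / (1 - z))`; `m2beta` is its exact inverse. Linear-model
#' comparators operate on M-values. The base of the logarithm only rescales
#' OLS coefficients; t statistics and p-values are invariant to it.
#'
#' @param z beta values strictly inside (0, 1) (clip boundaries first).
#' @param m M-values.
#' @return transformed vector/matrix of the same shape.
#' @export
beta2m <- function(z) {
  if (any(!is.finite(z)) || any(z <= 0) || any(z >= 1))
    stop("beta values must lie strictly in (0, 1); clip boundaries first")
  log2(z / (1 - z))
}

#' @rdname beta2m
#' @export
m2beta <- function(m) {
  1 / (1 + 2^(-m))
}

#' Per-CpG EWAS linear regression
#'
#' Ordinary least squares of each CpG's M-values on the design matrix, with a
#' two-sided t test of the phenotype coefficient on `n - ncol(X)` residual
#' degrees of freedom. One QR decomposition of the design is shared by all
#' CpGs.
#'
#' @param m_matrix `n x m` matrix of M-values (samples in rows).
#' @param X `n x (p + 1)` design matrix whose first column is the intercept
#'   and second column the phenotype of interest.
#' @param coef index of the tested column of `X` (default 2, the phenotype).
#' @return data frame with one row per CpG: `cpg_id`, `estimate`, `se`,
#'   `statistic`, `p_value`.
#' @export
ewas_fit <- function(m_matrix, X, coef = 2L) {
  m_matrix <- as.matrix(m_matrix)
  X <- as.matrix(X)
  n <- nrow(m_matrix); k <- ncol(X)
  if (nrow(X) != n) stop("m_matrix and X must have the same number of rows")
  qrX <- qr(X)
  if (qrX$rank < k) stop("design matrix is rank deficient")
  if (n <= k) stop("more parameters than samples")

  co <- qr.coef(qrX, m_matrix)                      # k x m
  res <- qr.resid(qrX, m_matrix)
  df <- n - k
  sigma2 <- colSums(res^2) / df
  xtx_inv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * xtx_inv[coef, coef])
  tstat <- co[coef, ] / se
  data.frame(
    cpg_id = colnames(m_matrix) %||% paste0("cpg", seq_len(ncol(m_matrix))),
    estimate = unname(co[coef, ]),
    se = unname(se),
    statistic = unname(tstat),
    p_value = unname(2 * pt(-abs(tstat), df = df)),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Inverse-variance-weighted region statistic
#'
#' Combines the per-CpG EWAS effect estimates of one region into a single
#' test, accounting for inter-CpG correlation: with
#' \eqn{\Omega = \mathrm{diag}(se)\, R\, \mathrm{diag}(se)}, the combined
#' estimate is \eqn{A = (1'\Omega^{-1}1)^{-1} 1'\Omega^{-1}\hat\beta} with
#' standard error \eqn{\sqrt{(1'\Omega^{-1}1)^{-1}}}, and \eqn{z = A/se} is
#' referred to the standard normal. This is the simplified known-variance
#' form of the inverse-variance-weighted meta-analysis statistic used by
#' distance-window DMR methods; it omits their candidate-region search and
#' shrinkage steps.
#'
#' @param beta_hats vector of `L` per-CpG effect estimates.
#' @param ses vector of `L` positive standard errors.
#' @param R `L x L` correlation matrix of the CpGs (symmetric, unit
#'   diagonal). In practice estimate it from the block's M-values; a small
#'   ridge (`1e-8`) is added to the diagonal before inversion.
#' @return list with `estimate`, `se`, `z`, `p_value`.
#' @export
dmrff_stat <- function(beta_hats, ses, R) {
  L <- length(beta_hats)
  if (length(ses) != L) stop("beta_hats and ses must have equal length")
  if (any(!is.finite(ses)) || any(ses <= 0)) stop("standard errors must be positive")
  R <- as.matrix(R)
  if (!isTRUE(all.equal(dim(R), c(L, L)))) stop("R must be ", L, " x ", L)
  if (!isTRUE(all.equal(R, t(R), tolerance = 1e-8))) stop("R must be symmetric")
  if (!isTRUE(all.equal(unname(diag(R)), rep(1, L), tolerance = 1e-6)))
    stop("R must have a unit diagonal")

  Omega <- diag(ses, L) %*% R %*% diag(ses, L)
  diag(Omega) <- diag(Omega) + 1e-8
  kap <- kappa(Omega, exact = TRUE)
  if (!is.finite(kap) || kap > 1e12)
    stop("Omega is numerically singular (condition number ", format(kap, digits = 3), ")")
  sol <- solve(Omega, cbind(1, beta_hats))
  denom <- sum(sol[, 1L])
  estimate <- sum(sol[, 2L]) / denom
  se <- sqrt(1 / denom)
  z <- estimate / se
  list(estimate = estimate, se = se, z = z,
       p_value = 2 * pnorm(-abs(z)))
}

# IVW test for one block given the block's M-values and the design:
# per-CpG EWAS, sample correlation of the M-values, combined z.
dmrff_block <- function(m_block, X, coef = 2L) {
  m_block <- as.matrix(m_block)
  ew <- ewas_fit(m_block, X, coef = coef)
  if (ncol(m_block) == 1L) {
    z <- ew$statistic
    return(list(estimate = ew$estimate, se = ew$se, z = z,
                p_value = 2 * pnorm(-abs(z))))
  }
  R <- cor(m_block)
  dmrff_stat(ew$estimate, ew$se, R)
}
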