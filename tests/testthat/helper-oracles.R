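# Shared helpers: independent oracles and small data builders.

# Independent univariate beta-regression oracle with the same
# parameterization (alpha_i = b * exp(gamma0 + x_i' gamma), dispersion b),
# but a completely separate code path: stats::dbeta for the likelihood and
# BFGS with numerical gradients for the optimization.
oracle_beta_reg <- function(z, X) {
  Xs <- X[, -1, drop = FALSE]
  nll <- function(th) {
    g0 <- th[1]
    gam <- th[seq_len(ncol(Xs)) + 1]
    b <- exp(th[length(th)])
    a <- b * exp(g0 + drop(Xs %*% gam))
    -sum(dbeta(z, a, b, log = TRUE))
  }
  start <- c(qlogis(mean(z)), rep(0, ncol(Xs)), log(10))
  fit <- optim(start, nll, method = "BFGS",
               control = list(reltol = 1e-12, maxit = 1000))
  list(par = fit$par, loglik = -fit$value)
}

# Samples from the Libby-Novick generalized beta via the gamma-ratio
# construction, written independently of rgbeta (used to cross-check the
# sampler and the density).
oracle_rgbeta <- function(n, alpha, beta) {
  L <- length(alpha)
  P <- vapply(alpha, function(a) rgamma(n, shape = a, rate = 1),
              numeric(n))
  Q <- rgamma(n, shape = beta, rate = 1)
  P / (P + Q)
}

# Draws a block's beta values from the regression model itself: binary
# phenotype, per-CpG intercepts gamma0, shared slope gamma1, dispersion b.
sim_from_model <- function(n, gamma0, gamma1, b, x = rep(c(0, 1), length.out = n)) {
  L <- length(gamma0)
  eta <- outer(gamma1 * x, gamma0, `+`)
  alpha <- b * exp(eta)
  P <- matrix(rgamma(n * L, shape = alpha, rate = 1), n, L)
  Q <- rgamma(n, shape = b, rate = 1)
  Z <- P / (P + Q)
  colnames(Z) <- paste0("cg", seq_len(L))
  list(Z = Z, X = cbind(1, x), x = x)
}

# Tiny annotation table on one or more chromosomes, positions 100 apart.
make_annotation <- function(m, chrom = "chr1") {
  data.frame(cpg_id = sprintf("cg%05d", seq_len(m)),
             chromosome = rep_len(chrom, m),
             position = as.integer(seq_len(m) * 100),
             stringsAsFactors = FALSE)
}
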