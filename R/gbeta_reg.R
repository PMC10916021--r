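# Generalized beta regression for one block of CpGs.
#
# Parameter vector layout, used everywhere below:
#   theta = (gamma0_1, ..., gamma0_L, gamma_1, ..., gamma_p, log_beta)
# with alpha_{il} = beta_b * exp(gamma0_l + x_i' gamma), the unique
# reparameterization satisfying logit(E Z_il) = log(alpha_il) - log(beta_b)
# = gamma0_l + x_i' gamma with a single block dispersion beta_b.

# Pre-digest a block's beta-value matrix into the constants the likelihood
# needs, so the optimizer loop touches only cheap terms.
digest_block <- function(Z) {
  Z <- as.matrix(Z)
  if (any(!is.finite(Z)) || any(Z <= 0) || any(Z >= 1))
    stop("block beta values must lie strictly in (0, 1); clip boundaries first")
  W <- qlogis(Z)
  list(W = W,
       T = log1p(rowSums(exp(W))),
       rowcon = -rowSums(W) - 2 * rowSums(log1p(-Z)),
       n = nrow(Z), L = ncol(Z))
}

#' Negative log-likelihood of a block's generalized beta regression
#'
#' Evaluates \eqn{-\sum_i \log f(Z_i \mid \alpha_i, \beta_b)} where
#' \eqn{\alpha_{il} = \beta_b \exp(\gamma_{0l} + x_i'\gamma)} and \eqn{f} is
#' the Libby--Novick density (see [dgbeta()]). Non-finite parameter values
#' yield `+Inf` rather than an error, so the function can be handed directly
#' to derivative-free optimizers.
#'
#' @param theta parameter vector `(gamma0_1..gamma0_L, gamma_1..gamma_p,
#'   log_beta)`.
#' @param Z `n x L` matrix of beta values in (0, 1) for one block.
#' @param X `n x (p + 1)` design matrix whose first column is the intercept;
#'   the intercept column is absorbed into the per-CpG `gamma0` terms.
#' @return a single number (the negative log-likelihood), `+Inf` if the
#'   parameters are out of range.
#' @export
block_negloglik <- function(theta, Z, X) {
  d <- digest_block(Z)
  X <- as.matrix(X)
  if (nrow(X) != d$n) stop("Z and X must have the same number of rows")
  if (!all(X[, 1L] == 1)) stop("first column of X must be the intercept")
  Xs <- X[, -1L, drop = FALSE]
  if (length(theta) != d$L + ncol(Xs) + 1L)
    stop("theta must have length L + p + 1 = ", d$L + ncol(Xs) + 1L)
  gbeta_block_nll(as.numeric(theta), Xs, d$W, d$T, d$rowcon)
}

# method-of-moments univariate beta fit for starting values
mom_beta <- function(z) {
  m <- mean(z); v <- var(z)
  nu <- m * (1 - m) / v - 1
  if (!is.finite(nu) || nu <= 0) nu <- 5
  c(a = m * nu, b = (1 - m) * nu)
}

# Maximum-likelihood fit of one block by Nelder-Mead with seeded jittered
# restarts. `null = TRUE` fixes the phenotype coefficient (first slope) at 0
# by dropping that design column from the free parameters.
fit_block <- function(Z, X, null = FALSE, seed = NULL, n_restarts = 2L,
                      reltol = 1e-8) {
  d <- digest_block(Z)
  X <- as.matrix(X)
  if (nrow(X) != d$n) stop("Z and X must have the same number of rows")
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient (constant phenotype or collinear covariates)")
  Xs_full <- X[, -1L, drop = FALSE]
  Xs <- if (null && ncol(Xs_full) >= 1L) Xs_full[, -1L, drop = FALSE] else Xs_full
  L <- d$L; p <- ncol(Xs)

  mom <- t(apply(as.matrix(Z), 2L, mom_beta))
  log_beta0 <- log(mean(mom[, "b"]))
  start <- c(log(mom[, "a"]) - log_beta0, rep(0, p), log_beta0)

  if (!is.null(seed)) set.seed(seed)
  starts <- list(start)
  for (r in seq_len(n_restarts))
    starts[[r + 1L]] <- start + rnorm(length(start), sd = 0.2)

  obj <- function(th) gbeta_block_nll(th, Xs, d$W, d$T, d$rowcon)
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      optim(s, obj, method = "Nelder-Mead",
            control = list(reltol = reltol, maxit = 200L * length(s))),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }

  if (is.null(best)) {
    warning("all optimizer restarts failed for this block")
    return(structure(list(gamma0 = rep(NA_real_, L), slopes = rep(NA_real_, p),
                          log_beta = NA_real_, loglik = NA_real_,
                          converged = FALSE, null = null,
                          n_restarts_used = n_restarts),
                     class = "gbeta_block_fit"))
  }
  th <- best$par
  structure(list(
    gamma0 = setNames(th[seq_len(L)], colnames(Z)),
    slopes = setNames(if (p) th[L + seq_len(p)] else numeric(0), colnames(Xs)),
    log_beta = th[L + p + 1L],
    loglik = -best$value,
    converged = best$convergence == 0L && is.finite(best$value),
    null = null,
    n_restarts_used = n_restarts), class = "gbeta_block_fit")
}

# Likelihood-ratio test of the phenotype coefficient for one block.
# statistic = 2 * (loglik_full - loglik_null), referred to chi-square(1).
lrt_block <- function(Z, X, seed = NULL, n_restarts = 2L) {
  full <- fit_block(Z, X, null = FALSE, seed = seed, n_restarts = n_restarts)
  null <- fit_block(Z, X, null = TRUE, seed = if (is.null(seed)) NULL else seed + 1L,
                    n_restarts = n_restarts)
  ok <- isTRUE(full$converged) && isTRUE(null$converged)
  stat <- p <- NA_real_
  if (ok) {
    raw <- 2 * (full$loglik - null$loglik)
    if (raw < -1e-4) {
      ok <- FALSE   # null beat the full model by more than numerical noise
    } else {
      stat <- max(raw, 0)
      p <- pchisq(stat, df = 1, lower.tail = FALSE)
    }
  }
  list(statistic = stat, p_value = p, fit_full = full, fit_null = null,
       converged = ok)
}

#' Fit a generalized beta regression to a block of CpGs
#'
#' Fits the joint Libby--Novick generalized beta model to the beta values of
#' one block of CpG sites, linking each CpG's mean to the covariates through a
#' logit link with per-CpG intercepts and block-shared slopes:
#' \deqn{\mathrm{logit}\,E(Z_{il}) = \gamma_{0l} + x_i'\gamma.}
#' Estimation is by maximum likelihood (Nelder--Mead with seeded jittered
#' restarts). For a single CpG this is univariate beta regression with a
#' logit mean link and dispersion `beta`.
#'
#' The first non-intercept term of the formula is taken as the phenotype of
#' interest: `summary()` reports the likelihood-ratio test of its coefficient
#' against the null fit with that coefficient fixed at zero (chi-square, 1 df).
#'
#' @param formula model formula. The response may be a matrix of beta values
#'   (e.g. `cbind(cg1, cg2) ~ sex + age`) or a single vector.
#' @param data data frame (or environment) holding the variables.
#' @param seed optional integer seed controlling the jittered restarts.
#' @param n_restarts number of additional jittered starting points (default 2).
#' @return an object of class `"gbeta_reg"` with `print`, `summary`, `coef`,
#'   `logLik`, `fitted`, `residuals`, `predict`, `simulate` and `anova`
#'   methods.
#' @examples
#' set.seed(7)
#' x <- rep(0:1, each = 60)
#' z <- rgbeta(120, alpha = c(6, 6), beta = 14)
#' z[x == 1, ] <- rgbeta(60, alpha = c(9, 9), beta = 14)
#' d <- data.frame(z1 = z[, 1], z2 = z[, 2], x = x)
#' fit <- gbeta_reg(cbind(z1, z2) ~ x, data = d, seed = 1)
#' summary(fit)
#' @export
gbeta_reg <- function(formula, data = parent.frame(), seed = NULL,
                      n_restarts = 2L) {
  mf <- model.frame(formula, data)
  Z <- as.matrix(model.response(mf))
  X <- model.matrix(attr(mf, "terms"), mf)
  if (colnames(X)[1L] != "(Intercept)")
    stop("the model must include an intercept")
  L <- ncol(Z); p <- ncol(X) - 1L
  if (nrow(Z) <= p + L + 1L)
    stop("too few samples for ", L, " CpGs and ", p, " covariates")
  if (is.null(colnames(Z)))
    colnames(Z) <- paste0("z", seq_len(L))

  fit <- fit_block(Z, X, null = FALSE, seed = seed, n_restarts = n_restarts)
  structure(list(
    coefficients = c(fit$gamma0, fit$slopes),
    gamma0 = fit$gamma0, slopes = fit$slopes,
    log_beta = fit$log_beta, beta = exp(fit$log_beta),
    loglik = fit$loglik, converged = fit$converged,
    n_restarts_used = fit$n_restarts_used,
    df = L + p + 1L, nobs = nrow(Z), L = L,
    Z = Z, X = X, seed = seed, n_restarts = n_restarts,
    call = match.call(), terms = attr(mf, "terms")),
    class = "gbeta_reg")
}

#' @export
print.gbeta_reg <- function(x, ...) {
  cat("Generalized beta regression (", x$L, " CpG",
      if (x$L > 1) "s", ", n = ", x$nobs, ")\n", sep = "")
  cat("Call: ", deparse(x$call), "\n\n")
  cat("Per-CpG intercepts (gamma0):\n")
  print(round(x$gamma0, 4))
  if (length(x$slopes)) {
    cat("Shared slopes (gamma):\n")
    print(round(x$slopes, 4))
  }
  cat("Dispersion beta:", format(x$beta, digits = 4),
      "  log-likelihood:", format(x$loglik, digits = 6),
      if (!x$converged) " (NOT converged)", "\n")
  invisible(x)
}

#' @export
coef.gbeta_reg <- function(object, ...) object$coefficients

#' @export
logLik.gbeta_reg <- function(object, ...) {
  structure(object$loglik, df = object$df, nobs = object$nobs,
            class = "logLik")
}

#' @export
fitted.gbeta_reg <- function(object, ...) {
  eta <- outer(drop(object$X[, -1L, drop = FALSE] %*% object$slopes),
               object$gamma0, `+`)
  colnames(eta) <- names(object$gamma0)
  plogis(eta)
}

#' @export
residuals.gbeta_reg <- function(object, ...) object$Z - fitted(object)

#' Predicted mean methylation from a generalized beta regression
#'
#' @param object a [gbeta_reg()] fit.
#' @param newdata optional data frame of covariates; defaults to the fitting
#'   data.
#' @param ... unused.
#' @return matrix of predicted means in (0, 1), one column per CpG.
#' @export
predict.gbeta_reg <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  tt <- delete.response(terms(object))
  X <- model.matrix(tt, model.frame(tt, newdata))
  eta <- outer(drop(X[, -1L, drop = FALSE] %*% object$slopes),
               object$gamma0, `+`)
  colnames(eta) <- names(object$gamma0)
  plogis(eta)
}

#' @importFrom stats simulate delete.response
#' @export
simulate.gbeta_reg <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  eta <- outer(drop(object$X[, -1L, drop = FALSE] %*% object$slopes),
               object$gamma0, `+`)
  alpha <- object$beta * exp(eta)            # n x L, per-sample shapes
  n <- nrow(alpha); L <- ncol(alpha)
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    P <- matrix(rgamma(n * L, shape = alpha, rate = 1), n, L)
    Q <- rgamma(n, shape = object$beta, rate = 1)
    Zs <- P / (P + Q)
    colnames(Zs) <- names(object$gamma0)
    out[[s]] <- Zs
  }
  if (nsim == 1) out[[1L]] else out
}

#' @export
summary.gbeta_reg <- function(object, ...) {
  nullfit <- fit_block(object$Z, object$X, null = TRUE,
                       seed = if (is.null(object$seed)) NULL else object$seed + 1L,
                       n_restarts = object$n_restarts)
  ok <- object$converged && nullfit$converged
  stat <- p <- NA_real_
  if (ok) {
    raw <- 2 * (object$loglik - nullfit$loglik)
    if (raw >= -1e-4) {
      stat <- max(raw, 0)
      p <- pchisq(stat, df = 1, lower.tail = FALSE)
    }
  }
  structure(list(fit = object, lrt_statistic = stat, p_value = p,
                 tested = if (length(object$slopes)) names(object$slopes)[1L] else NA_character_,
                 null_loglik = nullfit$loglik),
            class = "summary.gbeta_reg")
}

#' @export
print.summary.gbeta_reg <- function(x, ...) {
  print(x$fit)
  if (!is.na(x$tested))
    cat("\nLikelihood-ratio test of '", x$tested, "': chi-square = ",
        format(x$lrt_statistic, digits = 4), " (1 df), p = ",
        format.pval(x$p_value, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Likelihood-ratio comparison of nested generalized beta regressions
#'
#' @param object,... two nested [gbeta_reg()] fits (larger model first or
#'   second; order is detected from the number of parameters).
#' @return a data frame with the chi-square statistic, degrees of freedom and
#'   p-value.
#' @export
anova.gbeta_reg <- function(object, ...) {
  others <- list(...)
  if (length(others) != 1L || !inherits(others[[1L]], "gbeta_reg"))
    stop("supply exactly two gbeta_reg fits to compare")
  a <- object; b <- others[[1L]]
  if (a$df < b$df) { tmp <- a; a <- b; b <- tmp }
  stat <- max(0, 2 * (a$loglik - b$loglik))
  df <- a$df - b$df
  data.frame(statistic = stat, df = df,
             p_value = pchisq(stat, df = df, lower.tail = FALSE))
}
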