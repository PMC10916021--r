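test_that("negative log-likelihood matches the uniform and beta closed forms", {
  set.seed(1)
  z <- matrix(runif(30, 0.05, 0.95))
  X0 <- matrix(1, 30, 1)
  # gamma0 = 0, log_beta = 0 => alpha = beta = 1: the uniform, nll = 0
  expect_equal(block_negloglik(c(0, 0), z, X0), 0)

  # arbitrary theta against the closed-form univariate beta density
  x <- rnorm(30)
  X <- cbind(1, x)
  th <- c(0.4, -0.7, log(8))
  a <- 8 * exp(0.4 - 0.7 * x)
  expect_equal(block_negloglik(th, z, X),
               -sum(dbeta(drop(z), a, 8, log = TRUE)), tolerance = 1e-10)
})

test_that("likelihood is invariant to jointly permuting sample rows", {
  set.seed(2)
  sim <- sim_from_model(40, gamma0 = c(0.2, -0.1), gamma1 = 0.5, b = 15)
  th <- c(0.2, -0.1, 0.5, log(15))
  perm <- sample(40)
  expect_equal(block_negloglik(th, sim$Z, sim$X),
               block_negloglik(th, sim$Z[perm, ], sim$X[perm, ]),
               tolerance = 1e-10)
})

test_that("non-finite parameters give an optimizer-safe penalty, not an error", {
  set.seed(3)
  z <- matrix(runif(20, 0.1, 0.9))
  X <- cbind(1, rnorm(20))
  expect_identical(block_negloglik(c(NA, 0, 0), z, X), Inf)
  expect_identical(block_negloglik(c(0, Inf, 0), z, X), Inf)
  expect_identical(block_negloglik(c(0, 0, 1e4), z, X), Inf)
})

test_that("maximum likelihood recovers the generating parameters", {
  set.seed(4)
  sim <- sim_from_model(2000, gamma0 = 0.5, gamma1 = 0.8, b = 20)
  d <- data.frame(z = drop(sim$Z), x = sim$x)
  fit <- gbeta_reg(z ~ x, data = d, seed = 1)
  expect_true(fit$converged)
  expect_equal(unname(fit$gamma0), 0.5, tolerance = 0.1)
  expect_equal(unname(fit$slopes["x"]), 0.8, tolerance = 0.1)
  expect_equal(fit$log_beta, log(20), tolerance = 0.2)
})

test_that("nested fits are ordered and close under a true null", {
  set.seed(5)
  diffs <- replicate(10, {
    sim <- sim_from_model(300, gamma0 = c(0.3, 0.3), gamma1 = 0, b = 20)
    full <- gbdmr:::fit_block(sim$Z, sim$X, null = FALSE, seed = 1)
    null <- gbdmr:::fit_block(sim$Z, sim$X, null = TRUE, seed = 2)
    full$loglik - null$loglik
  })
  expect_true(all(diffs > -1e-4))
  expect_lt(median(diffs), 2)
})

test_that("a constant phenotype is rejected as rank deficient", {
  set.seed(6)
  z <- matrix(runif(50, 0.2, 0.8))
  X <- cbind(1, rep(1, 50))
  expect_error(gbdmr:::fit_block(z, X), "rank deficient")
  expect_error(ewas_fit(beta2m(z), X), "rank deficient")
})

test_that("the univariate fit matches an independent beta-regression oracle", {
  set.seed(7)
  sim <- sim_from_model(800, gamma0 = -0.4, gamma1 = 0.6, b = 12)
  d <- data.frame(z = drop(sim$Z), x = sim$x)
  fit <- gbeta_reg(z ~ x, data = d, seed = 3)
  ora <- oracle_beta_reg(drop(sim$Z), sim$X)
  expect_equal(unname(coef(fit)), ora$par[1:2], tolerance = 1e-3)
  expect_equal(fit$loglik, ora$loglik, tolerance = 1e-4)
})

test_that("Nelder-Mead and BFGS reach the same optimum", {
  set.seed(8)
  sim <- sim_from_model(400, gamma0 = c(0.2, 0.5), gamma1 = 0.3, b = 18)
  nm <- gbdmr:::fit_block(sim$Z, sim$X, seed = 1)
  d <- gbdmr:::digest_block(sim$Z)
  Xs <- sim$X[, -1, drop = FALSE]
  obj <- function(th) gbdmr:::gbeta_block_nll(th, Xs, d$W, d$T, d$rowcon)
  start <- c(nm$gamma0, nm$slopes, nm$log_beta) + 0.05
  bf <- optim(start, obj, method = "BFGS", control = list(reltol = 1e-12, maxit = 500))
  expect_equal(-bf$value, nm$loglik, tolerance = 1e-4)
  expect_equal(unname(bf$par), unname(c(nm$gamma0, nm$slopes, nm$log_beta)),
               tolerance = 0.01)
})

test_that("shifting the phenotype by a constant leaves the LRT unchanged", {
  set.seed(9)
  sim <- sim_from_model(300, gamma0 = c(0, 0.2), gamma1 = 0.4, b = 15)
  r1 <- gbdmr:::lrt_block(sim$Z, sim$X, seed = 5)
  X2 <- sim$X; X2[, 2] <- X2[, 2] + 10
  r2 <- gbdmr:::lrt_block(sim$Z, X2, seed = 5)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-2)
})

test_that("the null LRT distribution is chi-square with one degree of freedom", {
  set.seed(10)
  for (spec in list(list(g0 = 0.4, L = 1), list(g0 = c(0.1, 0.3, -0.2), L = 3))) {
    stats <- vapply(1:600, function(k) {
      sim <- sim_from_model(150, gamma0 = spec$g0, gamma1 = 0, b = 20)
      gbdmr:::lrt_block(sim$Z, sim$X, seed = k)$statistic
    }, numeric(1))
    expect_equal(mean(stats), 1, tolerance = 0.2)
    ks <- ks.test(stats, pchisq, df = 1)
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("a strong simulated effect is overwhelmingly significant", {
  cfg <- sim_config(signal_strength = 1, n_blocks = 1, n_reps = 1)
  ds <- simulate_dataset(cfg, seed = 44)
  r <- gbdmr:::lrt_block(ds$beta, cbind(1, ds$pheno$phenotype), seed = 2)
  expect_lt(r$p_value, 1e-6)
})

test_that("model methods are coherent: fitted, predict, residuals, simulate, anova", {
  set.seed(12)
  sim <- sim_from_model(300, gamma0 = c(0.2, -0.3), gamma1 = 0.7, b = 15)
  d <- data.frame(z1 = sim$Z[, 1], z2 = sim$Z[, 2], x = sim$x)
  fit <- gbeta_reg(cbind(z1, z2) ~ x, data = d, seed = 1)

  mu <- fitted(fit)
  expect_true(all(mu > 0 & mu < 1))
  expect_equal(qlogis(mu[1, ]), fit$gamma0 + fit$slopes["x"] * sim$x[1],
               ignore_attr = TRUE)
  expect_equal(residuals(fit), fit$Z - mu, ignore_attr = TRUE)
  expect_equal(predict(fit, newdata = data.frame(x = c(0, 1))),
               plogis(outer(c(0, fit$slopes["x"]), fit$gamma0, `+`)),
               ignore_attr = TRUE)

  zs <- simulate(fit, seed = 2)
  expect_equal(dim(zs), dim(fit$Z))
  expect_true(all(zs > 0 & zs < 1))
  # simulated data should have roughly the fitted group means
  expect_equal(colMeans(zs[sim$x == 0, ]), plogis(fit$gamma0),
               tolerance = 0.05, ignore_attr = TRUE)

  null <- gbeta_reg(cbind(z1, z2) ~ 1, data = d, seed = 1)
  a <- anova(fit, null)
  expect_equal(a$df, 1)
  expect_gt(a$statistic, 0)
  s <- summary(fit)
  expect_equal(s$lrt_statistic, a$statistic, tolerance = 0.05)
})
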