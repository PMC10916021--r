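test_that("moment matching recovers known beta shapes", {
  expect_equal(unname(beta_params_from_moments(0.5, sqrt(1 / 12))), c(1, 1),
               tolerance = 1e-9)
  # nu = 0.3 * 0.7 / 0.0025 - 1 = 83
  expect_equal(unname(beta_params_from_moments(0.3, 0.05)), c(24.9, 58.1),
               tolerance = 1e-9)
  expect_error(beta_params_from_moments(0.5, 0.6), "infeasible")
  # round trip: Beta(a, b) has the requested moments
  p <- beta_params_from_moments(0.22, 0.07)
  a <- p[["shape1"]]; b <- p[["shape2"]]
  expect_equal(a / (a + b), 0.22)
  expect_equal(sqrt(a * b / ((a + b)^2 * (a + b + 1))), 0.07)
})

test_that("chains at rho = 0 are independent and at rho = 0.8 calibrated", {
  set.seed(1)
  r0 <- replicate(100, {
    z <- simulate_block_chain(506, 2, 0.3, 0.05, rho = 0)
    cor(z[, 1], z[, 2])
  })
  expect_lt(mean(abs(r0)), 0.05)

  r8 <- replicate(100, {
    z <- simulate_block_chain(506, 3, 0.3, 0.05, rho = 0.8)
    c(cor(z[, 1], z[, 2]), cor(z[, 2], z[, 3]))
  })
  expect_gt(mean(r8), 0.75)
  expect_lt(mean(r8), 0.85)
})

test_that("the copula preserves the beta marginal down the chain", {
  z <- simulate_block_chain(10000, 3, 0.3, 0.05, rho = 0.7, seed = 4)
  p <- beta_params_from_moments(0.3, 0.05)
  ks <- suppressWarnings(ks.test(z[, 3], pbeta,
                                 shape1 = p[["shape1"]], shape2 = p[["shape2"]]))
  expect_gt(ks$p.value, 0.01)
  expect_equal(colMeans(z), rep(0.3, 3), tolerance = 0.005, ignore_attr = TRUE)
  expect_equal(apply(z, 2, sd), rep(0.05, 3), tolerance = 0.02,
               ignore_attr = TRUE)
})

test_that("group means respect the signal-strength definition", {
  cfg <- sim_config(signal_strength = 1, n_blocks = 2, n_reps = 1)
  ds <- simulate_dataset(cfg, seed = 6)
  x <- ds$pheno$phenotype
  sig_cols <- ds$truth$cpg_ids[[1]]
  expect_equal(mean(ds$beta[x == 1, sig_cols]), 0.35, tolerance = 0.01)
  expect_equal(mean(ds$beta[x == 0, sig_cols]), 0.30, tolerance = 0.01)

  null_ds <- simulate_dataset(sim_config(signal_strength = 0, n_reps = 1), seed = 7)
  xn <- null_ds$pheno$phenotype
  expect_equal(mean(null_ds$beta[xn == 1, ]), mean(null_ds$beta[xn == 0, ]),
               tolerance = 0.02)
})

test_that("the unbalanced design produces the requested group counts", {
  cfg <- sim_config(n_present = 422, n_absent = 84, n_reps = 1)
  ds <- simulate_dataset(cfg, seed = 8)
  expect_equal(sum(ds$pheno$phenotype == 1), 422L)
  expect_equal(sum(ds$pheno$phenotype == 0), 84L)
})

test_that("infeasible scenarios are rejected up front", {
  expect_error(sim_config(baseline_mean = 0.9, baseline_sd = 0.05,
                          signal_strength = 3), "leaves")
  expect_error(sim_config(baseline_mean = 0.5, baseline_sd = 0.7), "infeasible")
})

test_that("continuous phenotypes shift methylation with the phenotype", {
  cfg <- sim_config(continuous = TRUE, signal_strength = 1, n_blocks = 1,
                    n_reps = 1)
  ds <- simulate_dataset(cfg, seed = 9)
  x <- ds$pheno$phenotype
  expect_equal(length(x), 506L)
  # per-sample mean is baseline + signal * sd * x
  expect_gt(cor(x, rowMeans(ds$beta)), 0.5)
  r <- gbdmr:::lrt_block(ds$beta, cbind(1, x), seed = 1)
  expect_lt(r$p_value, 1e-6)
})

test_that("per-test false positive rates of the linear-model methods match alpha", {
  cfg <- sim_config(signal_strength = 0, n_blocks = 10, n_reps = 60,
                    correction = "per_test", seed = 21)
  out <- estimate_power_fpr(cfg, methods = c("ewas", "dmrff_simple"))
  for (i in seq_len(nrow(out)))
    expect_lt(abs(out$fpr[i] - 0.05), 3 * max(out$mc_se_fpr[i], 0.005))
})

test_that("the block model's false positive rate is calibrated at matched correlation", {
  # the generalized beta block model implies inter-CpG correlation close to
  # the mean methylation level; simulate at that correlation so the joint
  # model is approximately correctly specified
  cfg <- sim_config(signal_strength = 0, rho = 0.3, n_blocks = 10, n_reps = 40,
                    correction = "per_test", seed = 22)
  out <- estimate_power_fpr(cfg, methods = "gbdmr")
  expect_lt(abs(out$fpr - 0.05), 3 * max(out$mc_se_fpr, 0.01))
})

test_that("power rises with signal strength for every method", {
  grid <- c(0.1, 0.25, 0.6)
  pows <- sapply(grid, function(s) {
    cfg <- sim_config(signal_strength = s, n_blocks = 2, n_reps = 40,
                      correction = "per_test", seed = 23)
    out <- estimate_power_fpr(cfg)
    setNames(out$power, out$method)
  })
  for (meth in rownames(pows))
    expect_true(all(diff(pows[meth, ]) > -0.1))
})

test_that("the methods cross over with correlation as expected", {
  run_at <- function(rho, seed) {
    cfg <- sim_config(signal_strength = 0.2, rho = rho, n_blocks = 2,
                      n_reps = 50, correction = "per_test", seed = seed)
    out <- estimate_power_fpr(cfg)
    setNames(out$power, out$method)
  }
  lo <- run_at(0.1, 24)
  hi <- run_at(0.9, 25)
  # strong correlation: joint beta model beats per-CpG EWAS
  expect_gt(hi["gbdmr"], hi["ewas"])
  # the IVW meta-analysis statistic loses power as correlation grows
  expect_gt(lo["dmrff_simple"], hi["dmrff_simple"])
})
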