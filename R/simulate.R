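# Synthetic methylation data with beta marginals and a controlled adjacent
# correlation, plus the Monte-Carlo power/false-positive-rate harness.

#' Beta shape parameters matching a target mean and standard deviation
#'
#' Solves `a = mu * nu`, `b = (1 - mu) * nu` with
#' `nu = mu (1 - mu) / sigma^2 - 1`, so that `Beta(a, b)` has exactly the
#' requested moments. Feasibility requires `sigma^2 < mu (1 - mu)`.
#'
#' @param mean target mean in (0, 1).
#' @param sd target standard deviation.
#' @return named vector `c(shape1, shape2)`.
#' @examples
#' beta_params_from_moments(0.3, 0.05)   # c(24.9, 58.1)
#' @export
beta_params_from_moments <- function(mean, sd) {
  if (length(mean) != 1L || mean <= 0 || mean >= 1)
    stop("'mean' must lie in (0, 1)")
  if (length(sd) != 1L || !is.finite(sd) || sd <= 0)
    stop("'sd' must be positive")
  v <- sd^2
  if (v >= mean * (1 - mean))
    stop("infeasible moments: sd^2 must be below mean * (1 - mean) = ",
         format(mean * (1 - mean), digits = 4))
  nu <- mean * (1 - mean) / v - 1
  c(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

# --- Gaussian-copula latent correlation calibration ------------------------
#
# The chain uses a latent AR(1) normal process back-transformed through the
# Beta quantile function. The monotone transform attenuates correlation, so
# the latent correlation is calibrated by Gauss-Hermite quadrature to make
# the Pearson correlation on the beta scale hit the target.

.latent_cache <- new.env(parent = emptyenv())

# Pearson correlation of (g(X1), g(X2)) for standard bivariate normal with
# correlation r, where g = qbeta(pnorm(.), a, b).
beta_scale_cor <- function(r, a, b, gh) {
  if (r == 0) return(0)
  s <- sqrt(2) * gh$x
  gj <- qbeta(pnorm(s), a, b)
  inner <- outer(r * s, sqrt(1 - r^2) * s, `+`)          # node grid for X2
  G2 <- matrix(qbeta(pnorm(inner), a, b), length(s))
  w <- gh$w / sqrt(pi)
  Egg <- sum(w * gj * drop(G2 %*% w))
  mu <- a / (a + b)
  v <- a * b / ((a + b)^2 * (a + b + 1))
  (Egg - mu^2) / v
}

latent_rho <- function(a, b, rho) {
  if (rho == 0) return(0)
  key <- sprintf("%.10g_%.10g_%.10g", a, b, rho)
  hit <- .latent_cache[[key]]
  if (!is.null(hit)) return(hit)
  gh <- pracma::gaussHermite(64)
  f <- function(r) beta_scale_cor(r, a, b, gh) - rho
  upper <- 0.999999
  if (f(upper) < 0) {
    r <- upper   # target effectively unreachable; use the near-comonotone limit
  } else {
    r <- uniroot(f, c(0, upper), tol = 1e-8)$root
  }
  .latent_cache[[key]] <- r
  r
}

# latent AR(1) chain back-transformed through per-column beta quantiles;
# `shape1`/`shape2` may be scalars or length-n vectors (per-sample marginals)
copula_chain <- function(n, L, shape1, shape2, r_latent) {
  x <- matrix(0, n, L)
  x[, 1L] <- rnorm(n)
  if (L > 1L) {
    noise_sd <- sqrt(1 - r_latent^2)
    for (l in 2:L) x[, l] <- r_latent * x[, l - 1L] + noise_sd * rnorm(n)
  }
  matrix(qbeta(pnorm(x), shape1, shape2), n, L)
}

#' Simulate a chain of correlated beta-distributed CpG sites
#'
#' Generates `n` samples of `L` adjacent CpG sites. The first site is
#' `Beta(a, b)` with the requested mean and standard deviation; each
#' subsequent site is generated from its predecessor by a Gaussian-copula
#' autoregressive step whose latent correlation is calibrated (by
#' Gauss--Hermite quadrature) so the realized Pearson correlation between
#' adjacent sites on the beta scale targets `rho`. The copula preserves the
#' `Beta(a, b)` marginal of every site exactly.
#'
#' @param n number of samples.
#' @param L chain length (block size), `>= 1`.
#' @param mean,sd marginal mean and standard deviation of every site.
#' @param rho target adjacent Pearson correlation in `[0, 1)`.
#' @param seed optional integer seed.
#' @return `n x L` matrix of beta values in (0, 1).
#' @export
simulate_block_chain <- function(n, L, mean, sd, rho, seed = NULL) {
  if (length(rho) != 1L || rho < 0 || rho >= 1)
    stop("'rho' must lie in [0, 1)")
  if (length(L) != 1L || L < 1) stop("'L' must be >= 1")
  p <- beta_params_from_moments(mean, sd)
  if (!is.null(seed)) set.seed(seed)
  r <- latent_rho(p[["shape1"]], p[["shape2"]], rho)
  copula_chain(n, L, p[["shape1"]], p[["shape2"]], r)
}

#' Specify a simulation scenario
#'
#' Collects the parameters of one Monte-Carlo scenario: group sizes (binary
#' phenotype) or a standard-normal continuous phenotype, the baseline beta
#' marginal, the signal strength (group mean difference in units of the
#' common standard deviation), the target adjacent correlation, and the block
#' layout. Defaults mirror the simulation design the method was evaluated
#' under: 253 present / 253 absent samples (total 506), baseline mean 0.3 and
#' SD 0.05, correlation 0.8 within blocks of size 2, 500 replicates.
#'
#' @param n_present,n_absent group sizes for the binary phenotype design.
#' @param continuous if `TRUE`, use a standard-normal continuous phenotype of
#'   `n_present + n_absent` samples; the per-sample mean shifts by
#'   `signal_strength * baseline_sd * x`.
#' @param baseline_mean,baseline_sd marginal moments of the null methylation
#'   distribution; `baseline_sd^2` must be below
#'   `baseline_mean * (1 - baseline_mean)`.
#' @param signal_strength mean shift between phenotype groups in SD units
#'   (`>= 0`).
#' @param rho target adjacent correlation within blocks, in `[0, 1)`.
#' @param block_size CpGs per block.
#' @param n_blocks total number of blocks per simulated dataset.
#' @param n_signal_blocks how many of the blocks carry the signal (the rest
#'   are null); defaults to all of them when `signal_strength > 0`, else 0.
#' @param n_reps Monte-Carlo replicates.
#' @param alpha_level significance level.
#' @param correction `"per_test"` (each block at level `alpha_level`) or
#'   `"bonferroni"` (adjusted across blocks within each replicate).
#' @param seed integer seed; every replicate derives its own seed from it.
#' @return an object of class `"sim_config"`.
#' @export
sim_config <- function(n_present = 253L, n_absent = 253L, continuous = FALSE,
                       baseline_mean = 0.3, baseline_sd = 0.05,
                       signal_strength = 0.5, rho = 0.8, block_size = 2L,
                       n_blocks = 1L,
                       n_signal_blocks = if (signal_strength > 0) n_blocks else 0L,
                       n_reps = 500L, alpha_level = 0.05,
                       correction = c("per_test", "bonferroni"), seed = 1L) {
  correction <- match.arg(correction)
  stopifnot(n_present >= 1L, n_absent >= 0L, block_size >= 1L,
            n_blocks >= 1L, n_signal_blocks >= 0L, n_signal_blocks <= n_blocks,
            n_reps >= 1L, signal_strength >= 0, rho >= 0, rho < 1,
            alpha_level > 0, alpha_level < 1)
  # both group means must be beta-feasible with the common sd
  beta_params_from_moments(baseline_mean, baseline_sd)
  shifted <- baseline_mean + signal_strength * baseline_sd
  if (shifted >= 1 || shifted <= 0)
    stop("shifted group mean ", format(shifted), " leaves (0, 1)")
  if (signal_strength > 0) beta_params_from_moments(shifted, baseline_sd)

  structure(list(n_present = as.integer(n_present),
                 n_absent = as.integer(n_absent),
                 continuous = isTRUE(continuous),
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 signal_strength = signal_strength, rho = rho,
                 block_size = as.integer(block_size),
                 n_blocks = as.integer(n_blocks),
                 n_signal_blocks = as.integer(n_signal_blocks),
                 n_reps = as.integer(n_reps), alpha_level = alpha_level,
                 correction = correction, seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation scenario:\n")
  if (x$continuous)
    cat("  continuous phenotype, n =", x$n_present + x$n_absent, "\n")
  else
    cat("  binary phenotype, ", x$n_present, "/", x$n_absent,
        " present/absent\n", sep = "")
  cat("  baseline Beta(mean ", x$baseline_mean, ", sd ", x$baseline_sd,
      "), signal ", x$signal_strength, " SD, rho ", x$rho, "\n", sep = "")
  cat("  ", x$n_blocks, " block(s) of size ", x$block_size, " (",
      x$n_signal_blocks, " with signal), ", x$n_reps, " replicates, ",
      x$correction, " at ", x$alpha_level, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Simulate one methylation dataset from a scenario
#'
#' Lays `n_blocks` blocks of `block_size` CpGs on one synthetic chromosome
#' (consecutive positions, 50 bp apart within a block, 10 kb between blocks)
#' and draws beta values with [simulate_block_chain()]. In signal blocks the
#' two phenotype groups share the standard deviation and differ in mean by
#' `signal_strength * baseline_sd`; with a continuous phenotype the mean
#' shifts by `signal_strength * baseline_sd * x_i` per sample.
#'
#' @param config a [sim_config()] object.
#' @param seed optional override of `config$seed`.
#' @return list with `beta` (`n x m` matrix), `pheno` (data frame with the
#'   `phenotype` column), `annotation`, and `truth` (one row per block:
#'   `block_id`, `signal`, plus the member `cpg_ids`).
#' @export
simulate_dataset <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_present + config$n_absent
  L <- config$block_size
  m <- config$n_blocks * L
  shift <- config$signal_strength * config$baseline_sd

  p0 <- beta_params_from_moments(config$baseline_mean, config$baseline_sd)
  r0 <- latent_rho(p0[["shape1"]], p0[["shape2"]], config$rho)

  if (config$continuous) {
    x <- rnorm(n)
  } else {
    x <- rep(c(1, 0), c(config$n_present, config$n_absent))
  }

  signal_flags <- rep(FALSE, config$n_blocks)
  if (config$n_signal_blocks > 0) signal_flags[seq_len(config$n_signal_blocks)] <- TRUE

  beta <- matrix(NA_real_, n, m)
  for (b in seq_len(config$n_blocks)) {
    cols <- (b - 1L) * L + seq_len(L)
    if (!signal_flags[b] || config$signal_strength == 0) {
      beta[, cols] <- copula_chain(n, L, p0[["shape1"]], p0[["shape2"]], r0)
    } else if (config$continuous) {
      means <- config$baseline_mean + shift * x
      if (any(means <= 0) || any(means >= 1))
        stop("a per-sample mean left (0, 1); reduce signal_strength")
      nu <- means * (1 - means) / config$baseline_sd^2 - 1
      if (any(nu <= 0)) stop("infeasible per-sample beta moments")
      beta[, cols] <- copula_chain(n, L, means * nu, (1 - means) * nu, r0)
    } else {
      p1 <- beta_params_from_moments(config$baseline_mean + shift,
                                     config$baseline_sd)
      r1 <- latent_rho(p1[["shape1"]], p1[["shape2"]], config$rho)
      pres <- x == 1
      beta[pres, cols] <- copula_chain(sum(pres), L, p1[["shape1"]], p1[["shape2"]], r1)
      beta[!pres, cols] <- copula_chain(sum(!pres), L, p0[["shape1"]], p0[["shape2"]], r0)
    }
  }

  cpg_ids <- sprintf("cg%08d", seq_len(m))
  colnames(beta) <- cpg_ids
  rownames(beta) <- sprintf("s%04d", seq_len(n))
  block_of <- rep(seq_len(config$n_blocks), each = L)
  pos <- 1L + (block_of - 1L) * 10000L + (seq_len(m) - 1L - (block_of - 1L) * L) * 50L
  annotation <- data.frame(cpg_id = cpg_ids, chromosome = "chr1",
                           position = pos, stringsAsFactors = FALSE)
  truth <- data.frame(block_id = seq_len(config$n_blocks),
                      signal = signal_flags)
  truth$cpg_ids <- I(split(cpg_ids, block_of))

  list(beta = beta,
       pheno = data.frame(sample_id = rownames(beta), phenotype = x,
                          stringsAsFactors = FALSE),
       annotation = annotation, truth = truth)
}

#' Monte-Carlo power and false-positive rate of the competing methods
#'
#' For each replicate, simulates a dataset from `config`, runs the requested
#' methods (the generalized beta pipeline on beta values; EWAS and the IVW
#' region statistic on M-values), and counts significant CpGs inside
#' truth-signal blocks (power numerator) and truth-null blocks
#' (false-positive numerator). Power is the number of detected signal CpGs
#' divided by the total number of signal CpGs, averaged over replicates, and
#' likewise for the false-positive rate over null CpGs.
#'
#' Significance is per `config$correction`: each test at `alpha_level`
#' (`"per_test"`) or Bonferroni-adjusted across blocks (for EWAS: across
#' CpGs) within each replicate. The IVW comparator is applied to the true
#' simulated block layout, mirroring a distance-window region definition.
#'
#' @param config a [sim_config()] object.
#' @param methods subset of `c("gbdmr", "ewas", "dmrff_simple")`.
#' @param verbose print a progress line every 50 replicates?
#' @return data frame with one row per method: `method`, `power`, `fpr`,
#'   `mc_se_power`, `mc_se_fpr`, `n_reps`.
#' @export
estimate_power_fpr <- function(config,
                               methods = c("gbdmr", "ewas", "dmrff_simple"),
                               verbose = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  methods <- match.arg(methods, several.ok = TRUE)
  per_test <- config$correction == "per_test"
  alpha <- config$alpha_level

  pow <- fpr <- matrix(NA_real_, config$n_reps, length(methods),
                       dimnames = list(NULL, methods))
  for (rep in seq_len(config$n_reps)) {
    rep_seed <- (config$seed + 104729 * rep) %% .Machine$integer.max
    ds <- simulate_dataset(config, seed = rep_seed)
    signal_cpgs <- unlist(ds$truth$cpg_ids[ds$truth$signal])
    null_cpgs <- unlist(ds$truth$cpg_ids[!ds$truth$signal])
    X <- cbind(1, ds$pheno$phenotype)
    M <- beta2m(ds$beta)

    score <- function(sig_cpgs) {
      c(power = if (length(signal_cpgs)) mean(signal_cpgs %in% sig_cpgs) else NA_real_,
        fpr = if (length(null_cpgs)) mean(null_cpgs %in% sig_cpgs) else NA_real_)
    }

    for (meth in methods) {
      sig_cpgs <- switch(meth,
        gbdmr = {
          mds <- suppressWarnings(suppressMessages(
            methylation_dataset(ds$beta, ds$annotation, ds$pheno)))
          run <- suppressWarnings(
            gbdmr(mds, "phenotype", seed = rep_seed, correction = "bonferroni",
                  alpha_level = alpha))
          p <- if (per_test) run$results$p_value else run$results$p_adjusted
          hit <- !is.na(p) & p < alpha
          unlist(strsplit(run$results$cpg_ids[hit], ","))
        },
        ewas = {
          ew <- ewas_fit(M, X)
          p <- if (per_test) ew$p_value else adjust_pvalues(ew$p_value, "bonferroni")
          ew$cpg_id[!is.na(p) & p < alpha]
        },
        dmrff_simple = {
          pb <- vapply(seq_len(nrow(ds$truth)), function(b) {
            cols <- ds$truth$cpg_ids[[b]]
            dmrff_block(M[, cols, drop = FALSE], X)$p_value
          }, numeric(1))
          if (!per_test) pb <- adjust_pvalues(pb, "bonferroni")
          unlist(ds$truth$cpg_ids[!is.na(pb) & pb < alpha])
        })
      s <- score(sig_cpgs)
      pow[rep, meth] <- s["power"]
      fpr[rep, meth] <- s["fpr"]
    }
    if (verbose && rep %% 50L == 0L)
      message("replicate ", rep, "/", config$n_reps)
  }

  mc_se <- function(v) if (all(is.na(v))) NA_real_ else sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))
  data.frame(method = methods,
             power = colMeans(pow, na.rm = TRUE),
             fpr = colMeans(fpr, na.rm = TRUE),
             mc_se_power = apply(pow, 2L, mc_se),
             mc_se_fpr = apply(fpr, 2L, mc_se),
             n_reps = config$n_reps,
             row.names = NULL, stringsAsFactors = FALSE)
}
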