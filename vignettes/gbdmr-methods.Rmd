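---
title: "Detecting differentially methylated regions with generalized beta regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting differentially methylated regions with generalized beta regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbdmr)
```

## The problem

Array-based DNA methylation assays report, for each CpG site, a *beta value*:
the fraction of methylated signal, a ratio in [0, 1]. Phenotypes often act on
runs of neighbouring CpGs rather than isolated sites, so region-level tests
(DMR detection) can outperform the per-CpG linear-regression screen (EWAS).
Most region methods first fit per-CpG linear models on logit-transformed
M-values and then combine the summary statistics. This package instead models
a region's beta values *jointly*, on their natural scale, with a multivariate
generalized beta distribution, and tests the phenotype effect with a
likelihood-ratio test.

## The model

**Segmentation.** CpGs are ordered by chromosome and coordinate. Adjacent
pairs with Pearson correlation strictly above a threshold (default 0.5,
computed on beta values, pairwise-complete across samples) are chained into
blocks; every other CpG is a singleton block. Blocks never cross chromosome
boundaries, and the blocks partition the CpGs, so every site is tested exactly
once. Ties at exactly the threshold break the chain ("higher than" is read
strictly). No base-pair distance cap is applied by default — correlation is
the criterion — but `segment_blocks(max_gap = )` can additionally break
chains across large gaps for users who want distance-bounded regions.

**Block likelihood.** For a block of $L$ CpGs, the vector
$Z = (Z_1, \dots, Z_L)$ is modelled with the Libby–Novick generalized beta
distribution: $Z_l = P_l / (P_l + Q)$ with independent
$P_l \sim \Gamma(\alpha_l, 1)$ and one shared $Q \sim \Gamma(\beta_b, 1)$.
Every marginal is $\mathrm{Beta}(\alpha_l, \beta_b)$ — matching the definition
of a beta value — and the shared denominator induces positive dependence
between the CpGs of the block. For $L = 1$ this is ordinary beta regression.

**Link.** Each CpG's mean is linked to the design through a logit link with a
per-CpG intercept and block-shared slopes:
$$\mathrm{logit}\,E(Z_{il}) = \log \alpha_{il} - \log \beta_b
  = \gamma_{0l} + \gamma_1 x_{i1} + \dots + \gamma_p x_{ip},$$
so $\alpha_{il} = \beta_b \exp(\gamma_{0l} + x_i'\gamma)$ with a single
dispersion $\beta_b$ per block. A sample-specific dispersion would make this
reparameterization ill-defined, which is why the package uses one $\beta_b$
per block throughout.

**Test.** The phenotype of interest is the first non-intercept column of the
design. The null fit fixes $\gamma_1 = 0$; twice the log-likelihood gap is
referred to $\chi^2_1$. P-values are adjusted for multiple testing across the
blocks (Bonferroni by default; Holm and Benjamini–Hochberg are available).
Significant blocks with $L \ge 2$ are labelled DMRs, significant singletons
DMPs. Power comparisons count *CpGs inside significant blocks*, not regions,
because different methods delimit regions differently.

## Estimation details

* All density work is in log space (`lgamma`, `log1p`); the likelihood is
  finite for any beta value representable strictly inside (0, 1). Inputs at
  exactly 0 or 1 are clipped to $[10^{-6}, 1 - 10^{-6}]$ on ingestion and the
  clip count reported; the likelihood itself rejects boundary values.
* Maximization is Nelder–Mead with relative function tolerance $10^{-8}$ and
  at most $200 \times \dim$ iterations, identical for full and null fits so
  the likelihood-ratio difference is not a stopping artifact. Tests verify
  that BFGS reaches the same optimum.
* Starting values come from per-CpG method-of-moments beta fits:
  $\log \beta_b$ starts at the log mean of the per-CpG $\hat\beta_l$,
  $\gamma_{0l}$ at $\log\hat\alpha_l - \log\beta_b^{(0)}$, slopes at 0. Two
  additional jittered restarts (SD 0.2, seeded) guard against local optima;
  the best restart wins.
* The statistic is floored at zero; a pre-floor value below $-10^{-4}$ (the
  null fit beating the full fit beyond numerical noise) is declared a
  convergence failure, flagged, and propagated as a missing p-value rather
  than silently dropped.
* Reproducibility uses R's global RNG in the conventional way: each
  top-level entry point takes a `seed`, and per-block restart seeds are
  derived deterministically from it, so results are identical regardless of
  how many parallel workers fit the blocks.

## The simulation harness

`sim_config()` defaults encode the evaluation design: 253/253
present/absent samples (total 506), baseline marginal mean 0.3 and SD 0.05,
adjacent correlation 0.8 inside blocks of size 2, 500 Monte-Carlo
replicates, significance at 0.05. The baseline moments are a typical
partially-methylated CpG with array-scale noise; they are configuration
knobs, not constants. An unbalanced 422/84 design and a standard-normal
continuous phenotype (per-sample mean shifted by
`signal_strength * sd * x`) are supported. *Signal strength* is the group
mean difference in units of the common SD; the two groups always share
their SD.

Correlated chains are generated by a Gaussian copula: a latent AR(1) normal
process is back-transformed through the Beta quantile function, so every
column keeps its exact beta marginal. Because the monotone transform
attenuates correlation, the latent correlation is calibrated by
Gauss–Hermite quadrature so the realized Pearson correlation on the beta
scale targets `rho`; the tested contract is that the realized adjacent
correlation at $n = 506$ is within $\pm 0.05$ of the target. In the
continuous-phenotype mode the calibration is done once at the baseline
parameters and shared across samples; the per-sample shifts are small
relative to the marginal, and the same contract is exercised in the tests.

What the generator does *not* emulate: probe-level technical noise,
batch and cell-composition structure, long-range correlation decay with
distance, and the heavy CpG-density heterogeneity of real arrays. Passing
simulations therefore demonstrate the statistical behaviour of the methods
under controlled dependence, not end-to-end performance on raw array data.

Comparator methods run exactly as they would in practice: EWAS and the
inverse-variance-weighted (IVW) region statistic operate on M-values
($\log_2$ logit; the base only rescales coefficients, leaving t statistics
unchanged), while the block model consumes beta values. The IVW comparator
is deliberately the simplified known-variance statistic
$A / \sqrt{(1'\Omega^{-1}1)^{-1}}$ with $\Omega$ built from the EWAS
standard errors and the sample correlation of the block's M-values (plus a
$10^{-8}$ diagonal ridge); the published distance-window method adds a
candidate-region search and shrinkage that are out of scope here. Its
closed-form power under compound symmetry, `dmrff_power()`, explains the
characteristic power decay of meta-analysis statistics as inter-CpG
correlation grows: at $\rho = 1$ the $L$ estimates collapse to one
effective observation.

## Problem sizes used in the checks

The shipped test-suite and acceptance script exercise: a 1000-block
(2000-CpG) fully null genome at $\rho = 0.8$ with Bonferroni correction;
500-replicate power at signal strength 0.5; 1000-replicate null calibration
of the likelihood-ratio statistic under the block model at $n = 506$; and
smaller 40–100-replicate grids for the power crossover between methods.
These sizes give Monte-Carlo standard errors small enough for the
qualitative claims being checked while keeping a full run in the minutes
range on a single core.

## Known limitations

* **Dependence is not a free parameter.** With the marginals fixed, the
  shared-denominator construction pins the inter-CpG correlation near
  $\alpha/(\alpha+\beta)$ — roughly the mean methylation level. When the
  empirical correlation in a block is far above that value, the joint model
  is misspecified even though every marginal fits, and the $\chi^2_1$
  reference for the likelihood-ratio statistic (exact under the model, as
  the calibration tests verify) becomes anti-conservative per test. The
  test suite therefore checks per-test calibration at a correlation matched
  to the model's implied value, and checks the genome-scale Bonferroni
  behaviour, which is the protocol used for real analyses, directly.
* Blocks are fitted independently; correlation *between* blocks is ignored
  by the test and only enters through the multiple-testing correction.
* The likelihood-ratio test has one degree of freedom: the phenotype must be
  binary or continuous, not a multi-level factor.
* Non-convergent blocks are flagged with missing p-values and excluded from
  the Bonferroni count; they are never silently dropped from the output.
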