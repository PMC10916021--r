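# gbdmr: differentially methylated region detection via generalized beta regression

DNA methylation arrays (Illumina 450k/EPIC) report a *beta value* per CpG
site — the methylated fraction, a ratio in [0, 1]. Phenotype effects often
span runs of neighbouring, correlated CpGs, which per-CpG linear regression
(EWAS) tests one at a time and meta-analytic region methods combine only
after the fact. This package is for epigenetic analysts who want a
*model-based* region test that works directly on the beta scale.

## The method

1. **Segment.** CpGs are ordered by chromosome and coordinate; adjacent
   pairs with Pearson correlation > 0.5 (configurable) are chained into
   blocks, everything else stays a singleton. Blocks partition the CpGs.
2. **Model.** A block of $L$ CpGs is fitted jointly with the Libby–Novick
   generalized beta distribution, $Z_l = P_l/(P_l + Q)$ with
   $P_l \sim \Gamma(\alpha_l, 1)$ and a shared $Q \sim \Gamma(\beta_b, 1)$:
   every marginal is $\mathrm{Beta}(\alpha_l, \beta_b)$ and the shared $Q$
   carries the inter-CpG dependence. Means follow a logit link,
   $\mathrm{logit}\,E(Z_{il}) = \gamma_{0l} + x_i'\gamma$, with per-CpG
   intercepts and block-shared slopes.
3. **Test.** The phenotype coefficient $\gamma_1$ is tested by likelihood
   ratio against $\chi^2_1$; p-values are adjusted across blocks
   (Bonferroni by default). Significant multi-CpG blocks are DMRs,
   significant singletons DMPs.

Also included: a per-CpG EWAS comparator on M-values, the simplified
inverse-variance-weighted (IVW) region statistic with its closed-form power
under compound-symmetric correlation (`dmrff_power()`), and a Monte-Carlo
harness that simulates correlated beta-distributed methylation through a
calibrated Gaussian copula.

## Worked example

Simulate 20 two-CpG blocks (adjacent correlation 0.8, 253/253 samples), two
of them carrying a 0.6-SD group mean shift, and run the pipeline:

```r
library(gbdmr)

cfg <- sim_config(signal_strength = 0.6, rho = 0.8, block_size = 2,
                  n_blocks = 20, n_signal_blocks = 2, n_reps = 1)
ds  <- simulate_dataset(cfg, seed = 7)
mds <- methylation_dataset(ds$beta, ds$annotation, ds$pheno)
fit <- gbdmr(mds, phenotype = "phenotype", seed = 7)
summary(fit)
#> 20 blocks over 40 CpGs; 2 DMRs containing 4 CpGs; 0 DMPs; 0 unconverged
#>
#> Top significant blocks:
#>  block_id chromosome start   end block_size    gamma1  lrt_stat   p_adjusted
#>         1       chr1     1    51          2 0.1590589 108.43670 4.312557e-24
#>         2       chr1 10001 10051          2 0.1168995  56.41366 1.174422e-12
#>  label
#>    DMR
#>    DMR
```

Both planted blocks — and only those — come back as DMRs. `gamma1` is the
phenotype effect on the logit-mean scale (positive: hypermethylated in the
present group), `lrt_stat` the $\chi^2_1$ statistic, and `p_adjusted` the
Bonferroni-adjusted p-value; `write_results(fit, "out.tsv")` (or
`format = "bed"`) exports the table. For file-based input use
`read_methylation(beta.tsv, pheno.tsv, manifest.tsv)`, and for a single
region the model is available as a classic R fit:
`gbeta_reg(cbind(cg1, cg2) ~ sex + age, data = d)` with `summary`, `coef`,
`predict`, `simulate` and `anova` methods.

The analytic IVW power explains why meta-analytic region statistics fade as
correlation grows:

```r
dmrff_power(0.5, sigma_n = 1, L = 2, rho = 0)    # 0.109
dmrff_power(0.5, sigma_n = 1, L = 2, rho = 0.9)  # 0.081
```

A command-line front end for the pipeline, the simulation harness and the
power curves is in `inst/scripts/gbdmr.R`.

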