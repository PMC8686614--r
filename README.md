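# crtscreen

Conditional randomization testing for high-MOI single-cell CRISPR screens.

## What problem this solves

High multiplicity-of-infection CRISPR screens (CROP-seq, Perturb-seq and
relatives) deliver dozens of guide RNAs (gRNAs) per cell and read out the
transcriptome, to map candidate enhancers to the genes they regulate. Testing
a gRNA–gene association is statistically treacherous: gRNA *detection* is
itself a sequencing measurement, so technical factors — depth, batch, library
complexity — confound treatment and outcome. Parametric negative-binomial
(NB) regression adjusts for the confounders but is fragile to expression
model misspecification (dispersion errors alone inflate null p-values);
permutation-style methods are robust to the expression model but cannot
adjust for confounders.

`crtscreen` implements a conditional randomization test (CRT) that does
both. For cell $i$, let $Y_i$ be the gene's UMI count, $X_i\in\{0,1\}$ gRNA
presence, and $Z_i$ the technical factors. The propensity
$\pi_i = P(X_i=1\mid Z_i)$ is estimated by logistic regression; the null
distribution of the test statistic is built by redrawing
$\tilde X_i \sim \mathrm{Bern}(\hat\pi_i)$ independently per cell, holding
$Y$ and $Z$ fixed. The p-value is valid under $Y\perp X\mid Z$ regardless of
the expression distribution.

The statistic is a *distilled* NB z-score: covariate effects
$\log\mu_i = \beta_0 + Z_i^\top\gamma$ are fit once without the gRNA term
(dispersion fixed, `Var = mu + alpha*mu^2`), then a single coefficient
$\beta$ is refit with those effects as offsets. The refit log-likelihood
depends on $\beta$ only through gRNA-carrying cells, so each of the $B$
resamples costs a univariate Newton solve over a few dozen cells (C++).
A four-parameter skew-t fit to the $B$ resampled z-scores turns 500
resamples into precise tail p-values, with an add-one empirical fallback.

Also included: per-gene dispersion pooling via a kernel mean–dispersion
trend, candidate *cis* pair construction (1 Mb TSS window) and in-silico
negative-control pairs from genomic coordinates, KS-uniformity calibration
diagnostics with Bonferroni flagging, BH discovery calling at FDR 0.1, and a
synthetic-data generator reproducing the confounded design the method
assumes.

## Worked example

Simulate one gene and one gRNA under confounding with a true repression
effect, and test the pair:

```r
library(crtscreen)
cfg <- sim_config()
Z <- gen_covariates(1000, cfg, seed = 11)             # batch + log depth
x <- gen_grna_indicators(Z, cfg$tau, seed = 12)       # ~4% of cells
y <- gen_zinb_expression(Z, x, cfg$beta, alpha = 1,
                         effect = -2, seed = 13)      # 2 log-units repression
res <- run_crt_pair(y, x, Z, alpha = 1, B = 500, tail = "left", seed = 42)
round(c(z = res$observed_z, p = res$p_value), 4)
#>      z      p
#> -7.066  0.000
res$p_value
#> [1] 6.652547e-11
```

The observed z of −7.07 sits far in the left tail of the skew-t fit to the
500 resampled null z-scores, giving p ≈ 6.7e−11 — far below the 1/501
resolution a raw empirical null could provide. Under the null
(`effect = 0`) the same pipeline returns p = 0.79 on this seed, and across
repetitions its p-values are uniform; `run_calibration_study()` verifies
that across four generative settings (over/under-dispersed, zero-inflated)
the CRT stays calibrated while the fixed-dispersion parametric NB reference
does not:

```r
cs <- run_calibration_study(n_sim = 200, seed = 1)
subset(cs$summary, select = c(method, setting, ks_p_value, type1_at_05))
#>          method setting ks_p_value type1_at_05
#> 1           crt       1   7.18e-01       0.035
#> 2           crt       2   8.55e-01       0.060
#> 3           crt       3   8.31e-01       0.055
#> 4           crt       4   7.12e-01       0.050
#> 5 nb_parametric       1   2.31e-01       0.040
#> 6 nb_parametric       2   0.00e+00       0.350
#> 7 nb_parametric       3   8.88e-16       0.000
#> 8 nb_parametric       4   4.16e-03       0.100
```

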