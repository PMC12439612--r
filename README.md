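# pedgibbs

Bayesian estimation of genetic parameters for dairy buffalo traits with a
bivariate pedigree ("animal") model, comparing a linear and a threshold
treatment of a reproductive trait.

## The problem

Murrah buffalo breeding programs select sires for milk production (**MP**,
total lactation yield standardized to 305 days,
`MP305 = TMP + 5.42705 (305 - LL)`) while monitoring age at first calving
(**AFC**, months), a precocity trait recorded once per cow and only for a
subset of the herd. Both traits are modeled jointly as

```
y = X b + Z a + e,    a ~ N(0, G0 ⊗ A),    e ~ N(0, R0 ⊗ I)
```

with herd–year–season contemporary groups and a heterozygosity (heterosis)
covariate as fixed effects, and additive genetic effects correlated through
the numerator relationship matrix `A`. **Model 1** treats AFC as a
continuous Gaussian trait. **Model 2** dichotomizes AFC at the sample
median and fits it as a threshold (liability) trait: a latent Gaussian
liability with threshold 0 and residual variance fixed at 1, sampled by
truncated-normal data augmentation. A Gibbs sampler (implemented in C++)
draws all location effects, `G0` and `R0`; the package reports posterior
summaries with Geweke convergence diagnostics, heritabilities and genetic
correlations, sire breeding values with accuracies, Spearman rank-stability
analyses across selection scenarios, and a subsample t-test comparing the
two models' heritability chains.

Because the motivating records are not public, the package includes a
synthetic-herd generator with the same statistical shape (~40 sires, ~1,050
recorded cows, ~2,700 milk records, ~630 AFC records) and a truth ledger,
so every stage is testable end to end.

## Worked example

```r
library(pedgibbs)

herd <- simulate_herd(sim_config(seed = 1))
prep <- prepare_dataset(herd$phenotypes, herd$ped)
prep
#> Prepared dataset:
#>  MP records: 2528 in 107 contemporary groups
#>  AFC records: 564 in 71 contemporary groups (threshold 36.96 months)
#>  dropped records: 13

fit1 <- run_chain(prep, herd$ped, model_spec(1, 60000, 6000, 2, seed = 2))
fit2 <- run_chain(prep, herd$ped, model_spec(2, 60000, 6000, 2, seed = 3))
fit1
#> Bivariate animal model (Model 1, linear AFC)
#>  saved samples: 27000 | rows: 2528 | animals: 2452
#>  posterior means: h2_MP = 0.265, h2_AFC = 0.251, rg = 0.100
```

`h2_MP` and `h2_AFC` are the heritabilities (additive over additive +
residual variance; for Model 2 the AFC value is on the liability scale) and
`rg` the additive genetic correlation — here estimated from one herd
simulated at h² = 0.32 / 0.27 and rg = 0.15 (the posterior means scatter
around those values across replicate herds; the recovery tests in the
suite quantify the coverage). `summary_table(fit1)` prints the
variance components with posterior SDs, both 95% interval conventions and
Geweke z-scores; `ebv_report()`, `spearman_scenarios()`,
`ebv_descriptives()` and `compare_heritability()` produce the sire-ranking
and model-comparison tables. File-level drivers (`pipeline_prepare()`,
`pipeline_run()`, `pipeline_compare()`) read and write delimited text, and
`inst/scripts/pedgibbs.R` wraps them as `simulate` / `prepare` / `run` /
`compare` subcommands.

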