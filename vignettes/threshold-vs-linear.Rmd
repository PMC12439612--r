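---
title: "Linear and threshold animal models for milk yield and age at first calving"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linear and threshold animal models for milk yield and age at first calving}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedgibbs)
```

## The problem

Dairy buffalo breeding programs select sires on milk production while trying
not to erode reproductive precocity. Two traits carry that trade-off here:
**MP**, total lactation milk yield standardized to a 305-day lactation
(`MP305 = TMP + 5.42705 (305 - LL)`, the correction slope being a fixed
population constant), and **AFC**, age at first calving in months. MP is
recorded repeatedly (one record per lactation); AFC exists once per cow and
only for a subset. The two traits are analyzed jointly in a **bivariate
animal model**,

$$ y = X\beta + Za + e, \qquad
   a \sim N(0,\, G_0 \otimes A), \qquad e \sim N(0,\, R_0 \otimes I), $$

where $\beta$ holds herd–year–season contemporary-group effects and a linear
heterozygosity (heterosis) covariate per trait, $a$ holds a breeding value
for every pedigree animal and both traits, and $A$ is the numerator
relationship matrix. Two treatments of AFC are compared:

* **Model 1** — AFC as a continuous Gaussian trait;
* **Model 2** — AFC dichotomized at the sample median (class 1 = at or below
  the median, i.e. early calvers) and modeled as a **threshold (liability)
  trait**: an unobserved Gaussian liability crosses a fixed threshold at 0,
  the liability residual variance is fixed at 1 for identification, and the
  latent liabilities are sampled by truncated-normal data augmentation.

Inference is by Gibbs sampling. Estimands are the additive-genetic and
residual (co)variances, heritabilities $h^2 = \sigma^2_a/(\sigma^2_a +
\sigma^2_e)$, the additive genetic correlation $r_g$, sire breeding values
with accuracies $\sqrt{1 - \mathrm{PEV}/\sigma^2_a}$, Spearman rank
correlations of sire rankings between models under three selection
scenarios, and a Welch t-test comparing the two models' heritability chains
through 30 random subsamples of 2,700 saved cycles each.

## Data preparation

`prepare_dataset()` applies, in order: the 305-day standardization;
the heterozygosity covariate `HTZ = MS*OM + MM*OS` from the pedigree's
breed-composition fractions (0 for purebreds, 1 for an F1 cross); quarterly
calving seasons (Jan–Mar = 1, ..., Oct–Dec = 4); herd × year × season
contemporary groups, dropping groups with fewer than 3 records *together
with their records* (logged, never silent); and the median split of AFC.
Because AFC is recorded once per cow while MP repeats, contemporary groups
are formed separately per trait's record set — pooling them would discard
AFC records whenever milk recording was sparse in a cell. The boundary value
of the median split goes to class 1, the only class whose defining
inequality is stated strictly ("less than or equal"); the median itself is
computed after the group-size filter, on the records actually analyzed.

## The sampler

One Gibbs cycle updates, in order: latent liabilities (Model 2); each fixed
effect and each animal's bivariate breeding-value block from their Gaussian
full conditionals, using the observed-partition residual precision of each
record row and shrinkage through the sparse $A^{-1}$ (built by Henderson's
rules with Meuwissen–Luo inbreeding coefficients; an option disables
inbreeding for cross-checks); $G_0$ from an inverse-Wishart conditional with
scale `prior + a' A^{-1} a`; and $R_0$ from an inverse-Wishart conditional
after augmenting the unobserved trait's residual in single-trait rows.
Records enter as bivariate rows: each lactation is a row, and a cow's AFC
record rides on her first milk row, which also carries the (mild) residual
covariance between the traits.

Numerical choices worth knowing:

* **Identification of the threshold trait.** The threshold is fixed at 0 and
  the liability residual variance at 1. Rather than rescaling after an
  unconstrained draw — a transformation that is not a valid MCMC move and
  that we found drives the chain into degenerate regimes — the residual
  update for Model 2 draws the milk residual variance and the
  residual regression from their *exact conditional* under the
  inverse-Wishart (for a 2×2 inverse-Wishart, the conditional variance
  `r_mp.afc` and the regression `r_cov/r_afc` are independent of `r_afc`).
  An unconstrained mode (`fix_afc_residual = FALSE`) is available; its
  liability scale is only weakly identified and wanders, which is useful to
  illustrate why the constraint exists.

* **The extreme-category problem, and two guards.** With ~3–10 binary
  records per contemporary group, cell effects with flat (or very diffuse)
  priors can manufacture liability variance: a cell whose records happen to
  fall mostly in one class lets its effect and the members' breeding values
  grow together without any likelihood penalty, and the genetic variance
  ratchets upward. We verified with three independent implementations
  (the package sampler, a blocked Gibbs sampler, and a
  liability-marginalized probit Metropolis sampler) that this is a property
  of the posterior under weak cell priors, not a bug. The guards: (i)
  threshold-trait contemporary-group effects are treated as a *random*
  effect whose variance is itself sampled (scaled-inverse-chi-square
  hyperprior, df 4, scale 2 — prior mean 1 on the liability scale); and
  (ii) a joint Metropolis scale move proposes rescaling the entire AFC
  dimension (liabilities, cell effects, breeding values, the AFC row and
  column of $G_0$) at once. The breeding-value Jacobian cancels against the
  genetic-prior normalization, so the move is cheap, and it lets the chain
  traverse scale regimes in both directions instead of inflating one
  coordinate at a time. Linear traits keep flat fixed-effect priors
  throughout; the linear model gets the analogous (data-fixed) scale move
  on the AFC breeding values and variance, which frees the chain from the
  near-zero absorbing regime of a weakly informed genetic variance.

* **Priors.** Variance priors are inverse-Wisharts with df 3
  (dimension + 1) and scale half the *within contemporary-group*
  phenotypic variance per trait (liability variance taken as 1). Two
  points matter here. First, the scale must be computed within cells: the
  raw phenotypic variance is dominated by the herd/year spread the fixed
  effects absorb (two orders of magnitude for milk in the synthetic herd),
  and an inverse-Wishart scaled by it pushes the genetic variance far
  upward while looking "weak". Second, at df 3 the marginal prior on a
  variance is InvGamma(1, scale/2), whose scale sets the prior *median*
  directly; a very small scale is a strongly zero-attracting prior, which
  drags the posterior of a weakly informed trait (AFC here) to near-zero
  heritability for unlucky datasets. Half the within-cell variance puts
  the prior median near h-squared 0.35 with mass spread over (0.05, 0.9) —
  weakly informative in the sense that matters for calibration. The
  threshold-trait heterozygosity slope gets a proper N(0, 4) prior on the
  liability scale.

* **Warm-up and starting values.** Covariances start at 0.2 (additive)
  and 0.6 (residual) of the within-group phenotypic variance, and the
  first `warmup` cycles (default min(500, burn-in/2)) hold them fixed
  while the location effects adapt to the data. Without the warm-up, the
  first covariance update sees the all-zero starting breeding values as a
  null quadratic form and can trap a weakly informed trait's genetic
  variance near zero.

* **Randomness.** The sampler draws from a self-contained xoshiro256++
  stream seeded from the chain seed (normals by the polar method, gammas by
  Marsaglia–Tsang, deep-tail truncated normals by log-scale inversion), so
  a given `model_spec()` reproduces its chain bit for bit. The sampler
  draws on the order of $10^4$ variates per cycle, so per-draw cost
  matters.

* **Chain settings.** Production defaults mirror the motivating analysis:
  600,000 cycles, 60,000 burn-in, thinning 20, i.e. 27,000 saved samples.
  All validation in the test suite runs far shorter chains (12,000–25,000
  cycles), and the mixed-model-equation cross-check uses a long
  fixed-variance chain (4 million cycles, ~90 s) because its tolerance —
  half a percent of each effect's posterior SD — is a pure Monte-Carlo
  error bound, met with Rao-Blackwellized means (averages of the
  conditional means used at each update).

* **Intervals.** Posterior summaries report both the central 95% quantile
  interval (which respects the support of variances) and mean ± 1.96 SD
  (which can stray negative and is printed only for comparability with
  tables built that way).

## Diagnostics and comparison

`geweke_z()` compares the first 10% of a chain against the last 50%,
standardizing with spectral-density-at-zero estimates from a
Bartlett-tapered autocovariance sum (bandwidth 4% of the window). The 5%
two-sided cutoff is the convergence criterion; calibration on white-noise
chains is part of the test suite.

`compare_heritability()` implements the subsample t-test: 30 subsamples of
2,700 cycles drawn independently (they may overlap; each is drawn without
replacement), a mean per subsample, and a Welch t-test between models. A
caveat stated once and prominently: the subsample means from a single chain
are autocorrelated, so the nominal t distribution is approximate; the
procedure is reproduced as defined, and the test suite shows its behavior
under the null and under separation.

`ebv_report()` and `spearman_scenarios()` build the sire tables: scenario 1
is all sires with recorded progeny, scenario 2 those with positive milk EBV,
scenario 3 those with negative AFC EBV (signs of the *predicted breeding
values*, the reading consistent with the strictly negative AFC ranges such
tables show for scenario 3). Cells with fewer than 3 sires are reported as
undefined rather than estimated.

## The synthetic herd

Because the motivating dataset is not deposited, `simulate_herd()` generates
herds with the same statistical shape: ~40 sires, 350 founder dams, three
discrete generations of random mating (~2,500 pedigree animals, ~1,050
recorded cows), ~2,700 milk records (1–5 lactations per cow, mean ≈ 2.6),
and AFC recorded for ~60% of cows (~630 records), spread over 3 herds ×
6 years × 4 quarterly seasons. Breeding values descend the pedigree by
parent average plus Mendelian sampling with the exact
$d_i = 0.5 - 0.25(F_s + F_d)$ variance, so their covariance is exactly
$G_0 \otimes A$. The AFC residual is drawn jointly with the first-lactation
milk residual; total milk is back-computed from a drawn lactation length so
the 305-day correction is genuinely exercised. Default genetic parameters
are $h^2_{MP} = 0.32$, $h^2_{AFC} = 0.27$, $r_g = 0.15$, residual
correlation 0.10, phenotypic variances 2,512 kg² and 26.8 months², means
2,282 kg and 37.4 months; fixed-effect spreads (herd/year/season SDs of
400/150/80 kg and 2.0/1.5/1.0 months) and a heterosis slope of +150 kg and
−1.5 months per unit heterozygosity are one-time realism choices. An
earlier draft spread records over ten years; the resulting ~4-record
contemporary groups left AFC heritability unidentifiable — visible equally
in a REML fit — so the calendar span was consolidated once to the density
the record counts imply, and kept.

What the generator does *not* emulate: selection and non-random mating,
maternal and permanent-environment effects, lactation-curve shape,
seasonality of calving, and recording errors. Passing recovery tests on
these herds therefore shows the estimator is correct under the model's own
assumptions at a realistic size and design — not that the model is adequate
for any particular real population.

## Known limitations

* The threshold trait's contemporary-group variance and the guards above
  are load-bearing: with one binary record per animal, the liability-scale
  genetic variance is close to unidentified, and removing the hierarchical
  cell prior reintroduces the degeneracy. Estimates for such data are
  honest mostly through wide posteriors.
* Single-site location updates mix slowly relative to blocked solvers; the
  production chain length (600k cycles) is what makes them adequate.
* One chain per run; between-chain diagnostics (Gelman–Rubin) are out of
  scope, as are maternal effects, multi-threshold traits, REML, and genomic
  relationship matrices.

## A worked run

```{r, eval = FALSE}
herd <- simulate_herd(sim_config(seed = 1))
prep <- prepare_dataset(herd$phenotypes, herd$ped)
fit1 <- run_chain(prep, herd$ped, model_spec(1, 60000, 6000, 2, seed = 2))
fit2 <- run_chain(prep, herd$ped, model_spec(2, 60000, 6000, 2, seed = 3))
summary_table(fit1)
compare_heritability(fit1, fit2)
spearman_scenarios(ebv_report(fit1, herd$ped, prep),
                   ebv_report(fit2, herd$ped, prep))
```

`scripts/acceptance.R` runs exactly this workflow end to end and writes the
headline numbers as JSON.
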