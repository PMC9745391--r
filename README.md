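# coabund

Bayesian two-species N-mixture co-abundance models for camera-trap
count histories.

## What problem this solves

Standardized biodiversity surveys (camera traps, point counts, acoustic
monitors) yield *count histories* — individuals counted per sampling
unit and occasion — for many species at once. Inferring a directional
interaction between a dominant and a subordinate species (for example,
whether a predator suppresses a prey species across landscapes) from
such data is confounded by imperfect detection of both species, shared
responses to habitat covariates, *true zeros* where one species is
extirpated from entire landscapes, and overdispersed detections when
the species' densities differ by an order of magnitude. `coabund` is
for ecologists who want to estimate that interaction while handling all
four, with uncertainty propagated end to end.

## The model

For species *i* (dominant/subordinate), unit *j* in landscape
*ℓ(j)*, occasion *k*:

    N_ij  ~ Poisson(λ_ij · Z_ij)                       (iZIP abundance)
    log λ_dom,j = α₀ + α₁ FLII_j + α₂ HFP_j + α₃ℓ(j)
    log λ_sub,j = α₀′ + α₁′ FLII_j + α₂′ HFP_j + α₃′ℓ(j) + δ · N_dom,j
    n_ijk ~ Binomial(N_ij, p_ijk)                      (detection)
    logit p_ijk = β₀ + β₁ Effort_j + ε_ijk,   ε_ijk ~ Normal(0, τ_i)

`Z_ij` is an *informed* zero-inflation indicator fixed from data and
corroborated extirpation records (1 wherever the species was detected
in the landscape; 0 only at known absences), `α₃ ~ Normal(0, σ_land)`
is a landscape random intercept, and `ε` is an overdispersion random
effect (ODRE) per unit × occasion. The interaction `δ` — the effect of
the dominant species' latent abundance on the subordinate's
log-abundance — is the estimand: `δ < 0` with a 95% credible interval
excluding zero indicates top-down suppression. A Poisson detection
variant (`n ~ Poisson(N·r)`) is available for double-counting
sensitivity analyses, and the plain-Poisson / iZIP / ±ODRE variants can
be compared on equal terms.

Inference is by a slice-within-Gibbs MCMC sampler (Rcpp) with exact
enumeration updates for the discrete latent abundances; goodness of fit
is assessed by posterior predictive checks (chi-square discrepancy
Bayesian p-values and the overdispersion ratio c-hat). See the methods
vignette (`vignettes/coabundance-models.Rmd`) for the full account.

## Worked example

Simulate a ten-landscape study at the generator's default conditions
(rare dominant species extirpated from three landscapes, common
subordinate, true interaction δ = −0.2), fit the full model, and check
its fit:

```r
library(coabund)
sim <- simulate_dataset(sim_config(seed = 42))
fit <- fit_coabundance(sim$data, variant_spec("izip_odre"),
                       mcmc_settings(chains = 3, iterations = 2500,
                                     burn_in = 800, thin = 2, seed = 1))
s <- summarize(fit)
print(s[s$parameter %in% c("delta", "alpha_FLII[sub]", "alpha_HFP[sub]",
                           "beta1[sub]", "tau[sub]"), ], digits = 2)
posterior_predictive_check(fit, n_replicates = 500, seed = 2)
```

which prints

```
         parameter  mean   sd   q2.5  q97.5 rhat   pd clear_effect
5  alpha_FLII[sub]  0.64 0.11  0.431  0.860    1 1.00         TRUE
6   alpha_HFP[sub] -0.33 0.10 -0.535 -0.135    1 1.00         TRUE
29           delta -0.35 0.17 -0.706 -0.054    1 0.99         TRUE
33      beta1[sub]  0.24 0.10  0.036  0.447    1 0.99         TRUE
35        tau[sub]  0.28 0.17  0.012  0.647    1 1.00         TRUE

posterior predictive check ( 500 draws )
  dom: Bayesian p = 0.470 (good fit) | c-hat = 1.088
  sub: Bayesian p = 0.630 (good fit) | c-hat = 0.971
```

Reading it: the subordinate species increases with forest integrity
(FLII effect 0.64, CrI excluding 0) and decreases with human footprint;
detection rises with effort; and the interaction is clearly negative
(δ = −0.35, 95% CrI −0.71 to −0.05, 99% probability of direction),
covering the simulated truth of −0.2. All Rhat values are within the
1–1.2 convergence band, Bayesian p-values sit in the acceptable
.25–.75 range, and c-hat below 1.1 indicates no residual
overdispersion.

A command-line workflow covering the same ground — plus raw-record
preprocessing (30-min independence filter, daily aggregation to units,
5-day occasions, covariate standardization, zero-informant
construction) — is exposed through `inst/cli/coabund`:

```sh
Rscript inst/cli/coabund simulate --out_dir bundle --seed 1
Rscript inst/cli/coabund fit --bundle_dir bundle --out_dir fit1 --variant izip_odre --seed 1
Rscript inst/cli/coabund compare --bundle_dir bundle --out_dir cmp --seed 1
```

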