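# sealcarry

Carry-over effects of weaning size on adult reproductive performance in gray
seals (*Halichoerus grypus*) and similar long-lived capital breeders.

In colonies where females are individually marked as pups, measured for body
length at weaning (~4 weeks old), and then resighted every breeding season
for decades, two questions recur: do longer-weaned females **breed more
often** as adults, and do they **wean heavier pups**? `sealcarry` implements
both analyses as a tested, reusable pipeline:

* **Reproductive frequency** — a mixed-effects multistate mark-recapture
  model. A female's history runs over states F (first-time breeder),
  B (breeder) and N (nonbreeder), with

  `logit ψ[i,t]^{kB} = μ + λ1·z(age) + λ2·z(age)² + λ3,k + λ5·z(L_w) + β_i + θ_t`,

  sum-to-zero previous-state effects λ3, female and year random effects, and
  detection of breeders with probability `p` (nonbreeders are never sighted).
  The marginal likelihood over latent B/N sequences is computed exactly by a
  forward recursion in C++, and the posterior is sampled with an adaptive
  Metropolis-within-Gibbs sampler under the conventional priors
  (N(0, 1000) on regression terms, Unif(0, 10) on random-effect sds,
  Unif(0, 1) on `p`). Model variants: null, linear and quadratic length
  effects, length × parity, cohort offsets; compared by WAIC.

* **Provisioning performance** — a linear mixed model for pup weaning mass
  with the same covariate menu plus pup sex and parity group (1/2/3+), and
  crossed female and year random intercepts; fitted by maximum likelihood via
  `lme4`, compared by AIC and likelihood-ratio tests.

* **Cost of reproduction** — the posterior contrast `ψ^BB − ψ^NB`: negative
  values mean breeding last year lowers this year's breeding probability.

* **Synthetic colony generator** — the original monitoring data are held by
  the collecting agency, so the package generates colonies with the same
  statistical structure (staggered recruitment, truncated-normal weaning
  lengths with cohort shifts, latent breeding dynamics, imperfect detection,
  per-birth pup masses) and the test suite validates every stage by
  parameter recovery against known truth.

## Worked example

```r
library(sealcarry)

colony <- simulate_colony(sim_config(n_females = 200, n_occasions = 14, seed = 42))
#> <seal_colony> 200 females, 14 occasions, 1344 pup records

fit <- fit_multistate(colony, "linear",
                      mcmc_config(n_chains = 2, n_iter = 4000,
                                  burn_in = 2000, thin = 4, seed = 1))
transition_summary(fit)
#>   transition      mean         sd      q2.5       q50     q97.5
#> 1     psi_FB 0.8015217 0.12789933 0.4811665 0.8272113 0.9675099
#> 2     psi_BB 0.8860111 0.08426220 0.6756458 0.9037347 0.9839653
#> 3     psi_NB 0.8989986 0.07836774 0.6979021 0.9166944 0.9884227
cost_contrast(fit)
#> psi^BB - psi^NB: mean -0.01299  95% CRI [ -0.0822 , 0.04171 ]  P(<0) = 0.722
```

The transition rows are the posterior breeding probabilities for first-time
breeders, breeders and nonbreeders at mean age and mean weaning length; here
the contrast is mildly negative (a ~1% cost of reproduction, with posterior
probability 0.72 of being a cost at all). The weaning-length effect on the
logit of breeding (`lambda5`) has posterior mean 0.80 with 95% CRI
(0.55, 1.07) in this small synthetic colony — the generating value is 0.549.

```r
f0 <- fit_mass_model(colony$pups, colony$females, "null")
f1 <- fit_mass_model(colony$pups, colony$females, "linear")
f1
#> <mass_fit> variant: linear (ML) | n = 1344 | AIC = 6565.777
#>            term estimate     se
#>     (Intercept)   49.304 0.5254
#>           z_age   14.846 0.5047
#>          z_age2  -11.761 0.4147
#>   pup_sexfemale   -2.170 0.1405
#>   parity_group2    4.439 0.2853
#>  parity_group3+    6.387 0.3629
#>            z_lw    1.010 0.1619
#>   sd components: female 2.059 | year 1.195 | residual 2.39

likelihood_ratio_test(f0, f1)$p     # 2.5e-09: the length term is supported
variance_partition(f1)              # female 0.373, year 0.125, residual 0.502
predict_mass_spread(f1, 90, 132)    # 10.5 kg (95% CI 7.2-13.8)
```

So mothers at the long end of the weaning-length range are predicted to wean
pups ~10 kg heavier than mothers at the short end, and repeatable differences
among females account for ~37% of the variance in pup mass in this synthetic
colony.

`run_pipeline(run_config(...))` chains all of the above (simulate → write →
filter → fit both families → compare → report) into an artifact directory
with CSV tables, figures, a log, and a manifest recording the seed and
standardisation constants.

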