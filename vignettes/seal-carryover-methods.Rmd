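---
title: "Models and methods: weaning-size carry-over effects on reproductive performance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: weaning-size carry-over effects on reproductive performance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sealcarry)
```

## The scientific setting

Gray seals are long-lived capital breeders: a mother fasts through an intense
2-3 week lactation, so the mass of her pup at weaning is a direct measure of
the energy she transferred. On a closed breeding colony, individually branded
females can be followed for decades: each breeding season a female is either
sighted rearing a pup (scored 1) or not sighted (scored 0). `sealcarry`
implements a two-track analysis of how a female's *own* body length at
weaning (measured once, at ~4 weeks of age; `L_w`, in cm) carries over into
her adult reproductive performance:

1. **Reproductive frequency** — how often she returns to breed — via a
   multistate mark-recapture model with imperfect detection.
2. **Provisioning performance** — the weaning masses of her pups — via a
   linear mixed model with crossed female and year random intercepts.

Because the underlying long-term monitoring data are not publicly deposited,
the package ships a synthetic colony generator
(`sim_config()`/`simulate_colony()`) with the same statistical structure, and
the test suite establishes correctness by parameter recovery rather than by
re-analysis of the original records.

## The multistate breeding model

A female enters the study at *recruitment*, her first sighting with a pup.
She starts in state `F` (first-time breeder) and afterwards moves between
`B` (breeder) and `N` (nonbreeder). The probability of breeding in year `t`
given the previous state `k` is a mixed-effects logistic model:

$$\mathrm{logit}\,\psi^{kB}_{i,t} = \mu + \lambda_1 z(\mathrm{age}_{i,t}) +
\lambda_2 z(\mathrm{age}_{i,t})^2 + \lambda_{3,k} + \lambda_5 z(L_{w,i}) +
\beta_i + \theta_t,$$

with $\sum_k \lambda_{3,k} = 0$, $\beta_i \sim N(0, \sigma_\beta^2)$ and
$\theta_t \sim N(0, \sigma_\theta^2)$. Breeders are sighted with detection
probability $p$; nonbreeders are never sighted (they do not haul out with a
pup). Five fixed-effect structures are supported (`variant =` `"null"`,
`"linear"`, `"quadratic"`, `"parity"`, `"cohort"`), mirroring the usual menu:
no length effect, linear and quadratic length effects, a length-by-parity
interaction, and cohort offsets.

### Likelihood

Conditioning on first capture, the likelihood of a female's post-recruitment
sighting vector marginalises the latent `B`/`N` sequence exactly with a
two-state forward recursion (`forward_loglik()`, implemented in C++), using
the emission law $P(y{=}1\mid B) = p$, $P(y{=}1\mid N) = 0$. A brute-force
enumeration over all $2^T$ latent paths (`brute_force_loglik()`, pure R)
serves as an independent oracle; the suite checks agreement to $10^{-10}$ on
a thousand random histories. For the parity variant, parity is a function of
the latent path, so the forward pass runs on the expanded state space
(state × parity group 1/2/3+); parity here counts births *before* year `t`,
the recruitment birth included. An optional observation-level logit-normal
term with sd `sigma_omega` is supported in the simulator and in both
likelihood routes (marginalised by 15-node Gauss-Hermite quadrature); it
defaults to off and is not estimated, since the reported parameter set for
this model class does not include it and it is poorly separable from
$\sigma_\beta$ and $\sigma_\theta$ at these sample sizes.

### Priors and sampler

`fit_multistate()` uses the conventional priors for this model family:
diffuse $N(0, 1000)$ on all regression parameters, $\mathrm{Unif}(0,10)$ on
$\sigma_\beta$ and $\sigma_\theta$, and $\mathrm{Unif}(0,1)$ on $p$. The
sampler is an adaptive Metropolis-within-Gibbs scheme written for this
likelihood:

* fixed effects and $\mathrm{logit}(p)$ in one block with an adaptive
  multivariate-normal proposal (Haario-style empirical covariance, global
  scale tuned to 25% acceptance, a small diagonal floor so no coordinate can
  freeze);
* all female effects $\beta_i$ proposed jointly and accepted per female
  (valid because they are conditionally independent blocks);
* year effects $\theta_t$ as one joint block;
* Gibbs updates of $\sigma^2_\beta, \sigma^2_\theta$ from their truncated
  inverse-gamma conditionals;
* two *translation* moves ($\mu \to \mu+\delta$ with all $\beta_i$ or all
  $\theta_t$ shifted by $-\delta$), which leave the likelihood invariant and
  decorrelate the intercept from the random-effect means; and
* two *interweaved* (non-centred) scale moves that rescale a random-effect
  vector together with its sd, the standard remedy for the funnel coupling
  between a variance component and its effects.

All adaptation happens during burn-in only. The default protocol is 3 chains,
10,000 burn-in sweeps, 100,000 further sweeps thinned by 100 (3,000 retained
draws); convergence is flagged with the split-chain potential scale reduction
factor (`rhat()`), warning above 1.05. The test suite cross-checks the
sampler against an independent latent-state-augmentation implementation of
the same model in JAGS on a mid-sized synthetic colony with matched,
moderately informative priors (posterior means and sds must agree within a
fraction of the posterior spread), and verifies its calibration by a
prior-predictive check (no data ⇒ posterior = prior, Kolmogorov-Smirnov) and
by simulation-based calibration (uniform posterior ranks of generating
parameters over 50 replicate fits).

### What the posterior can and cannot pin down

A missed detection of a breeder looks, in the data, much like "skipped one
year and returned". With 19 occasions and several hundred females the main
mode dominates and $p$ is estimated to within ~0.02, but the posterior
retains a mild ridge along which $p$ falls and all breeding probabilities
rise; posterior means of $\lambda_5$, $\mu$ and $\sigma_\beta$ therefore sit
somewhat above the generating values at these sample sizes (an effect that
disappears when detection is perfect — verified against a marginal-ML mixed
logistic fit). In *short* observation windows (roughly fewer than ~12
occasions or ~150 females) the diffuse priors admit a second, saturated
regime — "every female breeds every year and detection equals the raw
resight rate" — and chains may visit it; fits to small colonies should use
tighter priors (`prior_sd_fixed`, `p_bounds` in `mcmc_config()`), as the
simulation-based-calibration tests do.

### Model comparison and the cost of reproduction

`waic()` computes the Widely Applicable Information Criterion from pointwise
log-likelihoods across draws; smaller is better. The pointwise unit defaults
to one female's full history, because occasions within a female are dependent
through $\beta_i$; a per-occasion option (forward-recursion increments
$\log P(y_t \mid y_{<t})$) is available for sensitivity. `cost_contrast()`
summarises the draw-wise difference $\psi^{BB} - \psi^{NB}$ at stated
covariates (default: standardised age and length 0, random effects 0, the
package's reporting convention throughout): a negative contrast means having
bred last year lowers this year's breeding probability — a cost of
reproduction expressed in breeding rate.

## The provisioning model

Pup weaning mass (kg) is modelled with `fit_mass_model()` as

$$mass_{j,t} = \pi_0 + \pi_1 z_2(\mathrm{age}_{i,t}) + \pi_2
z_2(\mathrm{age}_{i,t})^2 + \pi_{3,m} + \pi_4 I(\mathrm{sex}_j{=}\mathrm{f})
+ \pi_5 z(L_{w,i}) + \alpha_i + \eta_t + \upsilon_{j,t},$$

with parity group $m \in \{1, 2, 3{+}\}$ (`derive_parity()`), female and
year random intercepts and the same five-variant menu. Fitting is by maximum
likelihood via `lme4::lmer` (ML, not REML, by default so that
likelihood-ratio tests on fixed effects are valid; REML by flag);
`likelihood_ratio_test()` handles the nested pairs, `variance_partition()`
reports the shares of $\sigma_\alpha^2$, $\sigma_\eta^2$,
$\sigma_\upsilon^2$, and `predict_mass_spread()` converts the fitted length
effect into the expected mass difference between mothers at two weaning
lengths (Wald interval from the fixed-effect covariance).

Two conventions matter and are recorded on every fit and in run manifests:

* **Standardisation.** Weaning length and (in the multistate model) age are
  standardised to mean 0, sd 1 on the analysis sample. In the mass model,
  maternal age is standardised by *two* sample sds: with 1-sd scaling the
  quadratic age coefficients used as generating defaults (14.46, −11.88 kg)
  drive the implied mass surface negative at the edges of the observed age
  span, which no real pup satisfies; on the 2-sd scale the surface stays
  above ~19 kg everywhere. The generator and the fit share the convention,
  and raw-unit effects are always recoverable through the stored
  `standardizer` objects.
* **Variance components.** The generating defaults interpret the reported
  variance-component values for this system (4.67, 1.29, 5.45) as variances
  in kg²; that interpretation reproduces the reported ~41% individual and
  ~11% year shares of pup-mass variance, whereas reading them as sds does
  not. The same reading is used for the transition model's
  $\sigma^2_\beta = 0.895$ and $\sigma^2_\theta = 1.310$ (logit² scale).

The nesting order for LRTs is null ⊂ linear ⊂ {quadratic, cohort}. The
parity variant *replaces* the parity main effects with length-by-parity
interactions, so it has the same number of fixed effects as the null and is
not nested in it; it is compared by AIC only and
`likelihood_ratio_test()` refuses the pair.

## The synthetic colony

`simulate_colony()` generates, per female: a birth cohort (1998-2002 by
default, equal probabilities); a weaning length from a cohort-specific normal
truncated to 90-132 cm (means 112.0-114.1 cm, grand mean 112.7, sd 4.28 —
the most recent cohort deliberately longer, as observed in this system); an
age at recruitment from `(0.025, 0.314, 0.245, 0.286, 0.130)` over ages 4-8
(the printed recruitment fractions for ages 4-6, with the remaining mass
split over 7-8 so that 87% have recruited by age 7 — the tail shape is a
configuration choice); latent breeding dynamics at the reported
transition-model posterior means ($\mu = 1.686$, $\lambda_1 = 0.385$,
$\lambda_2 = -0.355$, $\lambda_3 = (-0.426, 0.138, 0.288)$ for F/B/N,
$\lambda_5 = 0.549$, $\sigma_\beta^2 = 0.895$, $\sigma_\theta^2 = 1.310$,
derived so that the implied mean transitions reproduce
$\psi^{FB} = 0.779$, $\psi^{BB} = 0.861$, $\psi^{NB} = 0.878$); detection of
breeders at $p = 0.975$; and a pup record with a mass drawn from the
provisioning model (defaults from the reported estimates; pup sex Bernoulli
0.5, which the source system does not contradict) for every *sighted*
breeding occasion. Latent states and all drawn random effects are returned
for truth-checking only, and every run writes a manifest with the seed and
standardiser constants.

The generator emulates: conditioning on first capture (the recruitment
sighting is forced), staggered entry, imperfect detection of breeders,
between-female and between-year heterogeneity on both traits, and the
length-fertility coupling. It does not emulate: mortality or permanent
emigration (the model class has no death state; adult survival in this
system is ~0.99/yr — an optional `survival` thinning exists for robustness
studies), brand misreads, density feedback, or selection on who recruits.
Passing recovery tests therefore demonstrates the estimators are correct for
the assumed process, not that the process captures every feature of field
data. Under the default truth the colony yields roughly 4,000-4,300 pup
records from 363 females — somewhat more than the ~3,457 such a study
reports, suggesting the real colony has additional heterogeneity the model
does not encode; the generating values were kept at the printed estimates
rather than tuned to match the pup count.

Two further protocol notes. The study filter (`filter_single_season()`,
females sighted in only one season are dropped) is applied in pipeline runs
as in the field protocol, but recovery and calibration tests run on
unfiltered colonies: the filter is a selection step that the likelihood does
not model, and recovery should test the model on its own assumptions.
Simulation-based calibration likewise draws generating parameters from a
narrower calibration prior shared with the sampler, since the diffuse
reporting priors generate degenerate all-breed or never-breed colonies.

## Problem sizes used by the tests and the acceptance script

The test suite uses: the full 363 × 19 study conditions for multistate
recovery (20 replicates, 2 chains × 6,000 sweeps after 2,500 burn-in,
thinned by 6) and for provisioning recovery (20 replicates); 250 × 14
colonies for the null-effect calibration of the length coefficient; 180 × 13
colonies for the WAIC/AIC selection replicates; 120 × 10 colonies for the
200-replicate uniformity check of the null LRT p-value; and 50 × 8 colonies
for the 50 simulation-based-calibration fits. `scripts/acceptance.R` runs
the full pipeline once at the study conditions with 3 chains × 20,000 sweeps
(6,000 burn-in, thinned by 20). These sizes are the package's choices for
routine verification; all of them scale up by changing `sim_config()` and
`mcmc_config()` arguments.

## Known limitations

* No death/emigration state and no trap-dependence in detection; histories
  are conditioned on first capture and truncated at the study end.
* $p$ is assumed constant across years and females (a single $p$ is what
  this model class reports); the detection/breeding ridge described above is
  the price of estimating it at all.
* The observation-level overdispersion term is simulated but not estimated.
* The cohort variant leaves the cohort offsets partially confounded with age
  and year effects (the first cohort is the baseline); with only five
  cohorts its WAIC is routinely worse, matching experience with this model
  family.
* The `L_w` standardisation constants of the original analyses are unknown,
  so effect sizes on the standardised scale are comparable only through the
  stored constants; the package reports raw-unit spreads
  (`predict_mass_spread()`) alongside.
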