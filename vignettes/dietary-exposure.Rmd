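---
title: "Bayesian dietary exposure assessment with dietex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian dietary exposure assessment with dietex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietex)
```

# The problem

Dietary exposure to a foodborne hazard is the product of two quantities
observed in two unrelated data sets: how much of the hazard is in the food
(occurrence: prevalence and concentration), and how much of the food people
eat and how often (consumption). Both data sets are typically small,
unbalanced and partly censored, so a credible assessment must carry
*uncertainty* (imperfect knowledge of parameters) separately from
*variability* (real heterogeneity across servings, days and consumers).
dietex does this with one joint Bayesian model: every data table contributes
a likelihood component, the posterior of all parameters is simulated by
MCMC, and exposure distributions are derived from the posterior draws so
that each draw indexes one possible variability distribution.

# The model

## Occurrence

Concentrations of a hazard in a food are log-normal: `log c ~ N(mu, sigma)`
per hazard-food pair. A measurement is *exact* when above the limit of
quantification (LOQ), *interval-censored* between the limit of detection
(LOD) and the LOQ, and a *non-detect* below the LOD. Censored records enter
the likelihood through the integrated probability mass of their interval,
never by substitution. Two interpretations of non-detects are supported:

* **Separate** (`occurrence_option = "separate"`): all records, even
  non-detects, are true positives; prevalence `q` is estimated from a
  separate binomial sample of positives. Likelihood components L1 (exact),
  L2 (interval), L3 (below LOD), L4 (binomial prevalence).
* **Zero-inflated** (`"zero_inflated"`): a unit is contaminated with
  probability `q`; non-detects may be true zeros. A non-detect contributes
  `1 - q(1 - F(log LOD))`, an interval record `q [F(log LOQ) - F(log LOD)]`
  and an exact record `q f(log c)` — the truncation of the detected-value
  density cancels against the detection probability (components L5-L7).

Priors: effectively flat (wide normal, sd 1000) for `mu`; Beta(1, 1) for
`q`; for `sigma` either a uniform on `(0, U)` or a gamma prior on the
precision. The upper bound `U` is a data-derived heuristic: five times the
standard deviation of the observed exact log values after appending two
pseudo-extremes `min - R` and `max + R`, `R = max(range, 1)` log unit. The
multiplier, floor and the pseudo-extreme rule are package choices (the
heuristic itself only fixes "a multiple of the augmented sd"); they are
configurable through `sigma_upper_bound()` and deliberately generous — the
bound exists to keep the prior proper, not to inform.

At least some exact values are required per pair: without them the
concentration distribution is not estimable, and the package refuses the
data rather than guessing.

## Consumption

Body weights are log-normal. Positive daily amounts per body weight are
log multivariate normal around a consumer-specific mean vector with
within-consumer (day-to-day) covariance `Cs`; consumer means are MVN around
the population mean `mu0` with between-consumer covariance `Cmu`. Zero
amounts are treated as missing, not as data: a day informs only the
marginal MVN of its positive coordinates, and an all-zero day contributes
nothing to the amount likelihood. Consumption frequency has two options:

* **Independent days**: Bernoulli consumption indicators with per-consumer
  frequencies whose logits are MVN around the population logits with
  covariance `Cp` (between-food frequency correlation).
* **Markov**: for consecutive-day diaries, a common two-state transition
  matrix per food (`p01`, `p11`) with uniform priors; the long-run daily
  consumption probability is `p01 / (p01 + p10)`. Transition probabilities
  are population-level, not per-consumer, and amounts on consumption days
  remain independent of the previous day.

The three covariance matrices get inverse-Wishart priors with `df = nf + 1`
and identity scale; this df is the choice under which the implied marginal
priors of all correlations are uniform on (-1, 1) (verified by a
prior-predictive test). The hyperparameters are a package decision —
"the usual Wishart priors" fix the family, not the constants.

True never-consumers are intentionally *not* modelled: with the few diary
days available per respondent a non-consumer mixture is not identifiable,
so low frequencies absorb committed zero-consumers.

## Sampling

The joint posterior factorises exactly into occurrence, body-weight,
amounts and frequency blocks (they share no parameters), so each block is
sampled from its own sub-posterior with its own seeded RNG stream. After
data augmentation — truncated-normal imputation of censored log
concentrations, a latent contamination indicator per non-detect
(zero-inflated option), and conditional-MVN imputation of zero (missing)
amount coordinates — every update is an exact conjugate Gibbs draw (normal
means, truncated-inverse-gamma or gamma variances, Beta prevalences and
transition probabilities, inverse-Wishart covariances), except the
per-consumer logit frequencies, which use an adaptive random-walk
Metropolis step (three sweeps per scan, step size tuned to ~35% acceptance
during burn-in). A gradient-based sampler was considered and rejected: the
conditional conjugacy makes Gibbs both simpler and exact on the conjugate
sub-models, which is what the distributional tests verify. Consequences of
this design worth knowing:

* on reduced models (prevalence-only, Markov-frequency-only) the draws are
  literally i.i.d. conjugate draws;
* the frequency hierarchy (`p0`, `Cp`) is the slowest-mixing block — with
  two binary observations per consumer the consumer logits are
  prior-dominated; effective sample sizes there are a fraction of the
  nominal draw count, and the default two chains with split-R-hat
  diagnostics (`diagnostics()`) make this visible;
* there is no automatic convergence stopping. Diagnostics only report;
  repeated runs of different lengths are the recommended check, and the
  heavily censored zero-inflated regime (which can produce bimodal
  posteriors of `q` and `mu`) is exactly where they matter.

Defaults: 2 chains, 2000 retained draws after 1000 burn-in. Initial values
are moment estimates (censored values at interval midpoints for
initialisation only), jittered across chains.

## Exposure composition

For a single hazard-food pair the composition is closed-form because
products of independent log-normals are log-normal:

* **Acute** (microbiological): a consumption-day serving of contaminated
  food gives `e+ = s * w * c ~ LN(mu0_j + mu_h + mu_w,
  Cs[j,j] + Cmu[j,j] + sigma_h^2 + sigma_w^2)`; per draw, the mean is
  `exp(ln_mu + ln_var/2)` and the median `exp(ln_mu)`.
* **Chronic** (chemical): concentration variability is replaced by the mean
  concentration `E(c) = exp(mu_h + sigma_h^2/2)`; the long-run mean
  exposure per body weight is `LN(mu0_j + Cs[j,j]/2 + log E(c), Cmu[j,j])`,
  so the only remaining variability is between consumers.

Acute chemical and chronic microbiological exposures are deliberately not
produced: occasional extremes average out for chemicals with long-run
effects, and a long-run mean of bacterial counts is not a meaningful risk
metric.

Multi-food totals have no closed form and are simulated per posterior draw
by the conditional sequence: consumer frequencies (logit-MVN, or the
stationary Markov probability), Bernoulli consumption indicators, consumer
mean vectors, day amounts with the full between-food covariance, body
weight, concentrations, and Bernoulli contamination indicators; the
per-food exposures are summed over the selected subset (the model is always
fitted on the full food set so all pairwise correlations are retained). For
microbiological hazards a final `Poisson(e)` draw converts the expected
count into a realised dose, which can be zero even for contaminated
servings. Under the Markov option the sampling sequence puts the single
population-level stationary probability into the per-consumer slot, so
between-consumer frequency variability vanishes there — a direct
consequence of modelling the transition probabilities as common parameters,
and worth remembering when comparing the two frequency options.

Adjustment (processing) factors are constants per hazard-food pair: a
concentration factor > 0 (added as its log to `mu_h` everywhere it
appears) and a prevalence factor in [0, 1] (multiplying `q`, clipped).
They carry no uncertainty by design.

## Uncertainty summaries

* **Overlay plots** show the variability CDF at ~20 randomly chosen
  posterior draws (count configurable) — enough to see the envelope
  without overplotting.
* **Posterior predictive** distributions draw one consumer per posterior
  draw (`n_U` simulations total) and are tabulated at the seven quantiles
  1, 5, 10, 50, 90, 95, 99%.
* **Two-dimensional summaries** (`two_dim_summary()`) separate the two
  layers: per draw, the variability quantile `gamma` is computed in closed
  form (`exp(mu + z_gamma sigma)`, e.g. `exp(mu + 1.64 sigma)` at 95%) for
  single pairs, or empirically from `n_V` inner simulations (default
  10^4) for totals; the 5% and 95% points of the per-draw quantiles give
  90% uncertainty bounds. For simulated totals the outer loop defaults to
  a subsample of up to 200 draws — the inner Monte Carlo error shrinks as
  `1/sqrt(n_V)` and dominates well before the outer count matters.

# The synthetic data generator

`default_truth()` ships two fully documented parameter sets that exercise
every model component; `generate_dataset()` inverts the model exactly
(log-normal draws thresholded at LOD/LOQ, Bernoulli contamination,
MVN consumption hierarchy, Markov chains started from their stationary
distribution), which is what makes parameter-recovery testing meaningful.

* **chemical-like** — a cadmium-like contaminant (mg/kg) in cereal and
  leafy vegetables: concentration medians 0.05 and 0.034 mg/kg with log-sd
  0.6/0.7, prevalences 0.30/0.45 informed by a separate 100-unit binomial
  sample per pair, LOD/LOQ at the 15%/30% quantiles of the positive
  distribution (~30% censored records), 200 respondents with two
  independent diary days, frequencies 0.7/0.5 with logit-scale variance 0.5
  and positive correlation.
* **micro-like** — a campylobacter-like organism (CFU/g) in raw foods
  (broiler meat, raw milk): median 10 and 4.5 CFU/g with log-sd 1.2/1.0,
  high prevalence 0.8/0.7 as is realistic for raw products, zero-inflated
  occurrence (~32% censored records), and a two-day consecutive diary with
  Markov transitions (p01 = 0.3/0.2, p11 = 0.7/0.6).

Shared choices a nutrition survey would recognise: body weight log-normal
around 75 kg (log-sd 0.2); population amounts near 1.35 and 0.8 g per kg
body weight per day with day-to-day log-sd ~0.63, between-consumer log-sd
0.5, and positive between-food correlations. The parameter magnitudes are
plausible stand-ins assembled for demonstration and testing, not fits to
any national survey, and the generator makes no attempt to mimic survey
weighting, recipe decomposition, or reporting error. Low-prevalence
zero-inflated data (mostly non-detects) can be generated and fitted but are
not a preset: in that regime the joint posterior of `(q, mu)` is weakly
identified and may be bimodal, so interval-coverage benchmarks are not
meaningful there — a dedicated robustness test only checks that such runs
complete and that multi-chain diagnostics expose the disagreement.

What passing tests on these presets show — and what they do not: recovery
of every generator scalar by 95% credible intervals in at least 80% of 20
seeded replicates demonstrates that the inference machinery is calibrated
*when the model is true*. Real occurrence and consumption data add
model misspecification (non-log-normal tails, reporting error, survey
design effects) that no synthetic test can rule out; the model-versus-data
graphics (`plot_concentration_fit()`, `empirical_cdf_bounds()`,
`bootstrap_pseudo_exposure()`) exist precisely for that judgement.

# Numerical choices

* Censored-interval probabilities are computed from `pnorm` log-CDFs with
  complementary forms chosen by the interval's position, avoiding
  catastrophic cancellation in the tails (verified to 1e-8 relative error
  against numerical integration).
* Logit and log transforms are clamped 1e-12 away from their boundaries.
* Degenerate covariances (zero variance components) fall back to an
  eigendecomposition square root so closed-form limits remain simulable.
* Likelihoods return `-Inf`, never `NaN`, for impossible parameter/data
  combinations, so samplers and optimisers can treat them as soft
  rejections.
* `sample_posterior(..., fixed = list(C_mu = ...))` pins covariance
  matrices for sensitivity analysis; the hierarchy-collapse test uses it
  to compare against the pooled closed form.
* Problem sizes in the test-suite: the recovery benchmark uses the preset
  sizes (200 respondents, 2 days, 300 occurrence records) with single
  chains of 800 retained draws per replicate, and the distributional
  equivalence checks use 10^5 simulated consumers; these sizes give Monte
  Carlo error comfortably below the tested tolerances.

# A worked example

```{r example, eval = FALSE}
library(dietex)

truth <- default_truth("micro-like")
d <- generate_dataset(truth, seed = 1)

spec <- model_spec(d, occurrence_option = "zero_inflated",
                   frequency_option = "markov",
                   hazard_type = "microbiological",
                   chains = 2, iter = 1500, burnin = 500, seed = 1)
fit <- sample_posterior(d, spec)
tidy(fit)

pred <- predictive_exposure(fit, "campylobacter_like")
predictive_quantiles(pred$dose)
plot_exposure_cdf(fit, "campylobacter_like", "broiler_meat")
```

# Known limitations

* No growth/inactivation or process modelling between measurement and
  consumption; adjustment factors are the only lever, and they are
  constants.
* No covariate regression for consumption (stratify and re-run instead),
  no survey weights, no recipe decomposition.
* No plate-count or dilution-series microbiological likelihoods; data must
  be concentrations with LOD/LOQ.
* The bimodal heavily-censored zero-inflated regime is reported, not
  resolved (no tempering); expect wide or multimodal posteriors there.
* Units are never converted: every output inherits the units of the input
  concentration and amount columns.
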