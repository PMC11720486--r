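---
title: "Models and methods behind awarekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind awarekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(awarekit)
```

`awarekit` analyses masked-priming experiments in which both objective
(forced-choice) and subjective (PAS) measures of prime awareness are
collected. This vignette documents the models, their assumptions, the
defaults and the numerical choices, in the order data flow through the
pipeline.

## 1. The synthetic experiment generator

Every downstream analysis assumes, implicitly or explicitly, a perceptual
model. The generator makes that model explicit so each stage can be
validated by parameter recovery. On each trial a bivariate percept is
drawn on an *identity evidence* axis (square vs diamond) and an
*awareness evidence* axis, from the Gaussian distribution of the trial's
stimulus class. The prime-absent (catch) class is anchored at mean (0, 0)
with unit variances; that anchor defines the scale of both axes.

* The forced-choice response is the percept's side of an identity
  criterion; the PAS rating is the bin of the awareness percept among
  three increasing cutpoints (defaults 0.85, 1.75, 2.6, chosen so a
  present-class awareness mean of 0.4 reproduces the heavily PAS-1-skewed
  report distributions typical of strongly masked primes).
* Attention differs by task: present-class mean vectors are multiplied by
  a block scale (defaults 0.8 single-task, 1.0 multiple-task, 1.5
  visibility block, encoding that primes are ignored in the single task
  and fully attended when visibility is probed) and by a per-participant
  attention factor `kappa ~ logNormal(0, 0.3)`, which makes some
  participants genuinely more aware than others on *both* axes — the
  between-subject spread the measurement-error regression needs.
  A participant-level awareness offset `Normal(0, 0.3)` additionally
  shifts PAS behavior (a report trait) without changing discrimination.
* RTs are `(base + effect) * exp(Normal(0, sdlog) - sdlog^2/2)`:
  multiplicative, right-skewed, mean-one noise, so the expected
  congruency effect equals the programmed one exactly. The effect on
  incongruent trials is `alpha + beta * a`, where `a` is the awareness
  percept relative to the participant's no-prime baseline; `alpha` (ms)
  is a true unconscious effect and `beta` (ms per unit awareness
  evidence) is awareness-driven priming. The defaults `alpha = 0`,
  `beta = 30` produce single-task effects of ~8-10 ms that vanish at
  zero awareness — the configuration the analyses are designed to
  distinguish from `alpha > 0`.
* Catch trials draw percepts from the absent class but still record a
  probe response and RT, keeping all blocks structurally identical.

Seeding is counter-based per participant, so a cohort can be extended
without reshuffling existing participants, and any participant can be
regenerated in isolation.

What the generator does **not** emulate: RT autocorrelation and fatigue,
block-order effects, criterion drift over time, response omissions, and
any non-Gaussian percept structure. Passing recovery tests therefore
shows the estimators are correct *under the stated model*, not that real
data satisfy it.

The display-timing arithmetic treats nominal millisecond durations as
frame counts on a 75 Hz monitor (13.33 ms frames): "67 ms" is five
frames, "13 ms" one, "53 ms" four. Both masking settings (ISI 0 + mask
67; ISI 13 + mask 53) then yield the same 107 ms prime-to-probe SOA; the
naive sum of the rounded labels would give 106 for the second setting.

## 2. Trimming, selection, exclusion

`trim_rts()` applies, in order: (1) drop probe-incorrect trials (RT
analyses only); (2) drop RTs below 200 ms or above 2000 ms, keeping exact
boundary values; (3) drop trials outside mean ± 2 SD, with the mean and
SD computed on the survivors of step 2, per participant-block (not per
condition), in a single pass. Step 3 is deliberately not iterated.
An empty survivor set after step 2 is an error (the SD is undefined), not
a silent empty result. In the multiple-task block the SD pass runs before
PAS-1 selection by default; `select_pas1()` can be applied first when the
analyst prefers trimming within the subjectively unseen subset.

Participants are excluded when probe accuracy in the multiple-task block
is strictly below 75%, or when strictly more than 10% of catch trials in
either the multiple-task or visibility block receive PAS-4 ("clear
perception") reports — evidence the scale was misused. Missing blocks
yield `NA` flags, never a silent `FALSE`.

Note that mean ± 2 SD trimming on right-skewed RTs slightly shaves a true
congruency effect (the incongruent distribution reaches further into the
trimmed tail); the calibration harnesses therefore compute effects on
untrimmed simulated data, where there are no artifact trials to remove.

## 3. Sensitivity measures

Objective counts treat square primes as signal and "square" responses as
the signal response; subjective counts treat PAS >= 2 on prime-present
trials as hits and on catch trials as false alarms. `dprime()` uses the
yes/no convention `d' = z(H) - z(F)`, `c = -(z(H) + z(F))/2` for both, so
the two measures live on one metric; no sqrt(2) correction is applied to
the forced-choice data because the comparison requires a common
convention. The log-linear correction (+0.5 per cell, +1 per denominator)
is applied *unconditionally*, keeping the estimate finite and continuous
in the counts; the uncorrected rates and d' are reported alongside.
Group-level d' is always the mean of per-participant d's, never the d' of
pooled counts.

## 4. Default Bayes factors

*t tests.* `jzs_ttest_bf()` integrates the noncentral-t likelihood over a
Cauchy(0, r) prior on the standardized effect (default r = sqrt(2)/2),
via the substitution `delta = r tan(phi)` which maps the real line to a
finite interval with an exactly constant prior factor `1/pi`. Quadrature
is adaptive with relative tolerance 1e-8 and the residual error is
reported as a percentage. Tests are two-sided by default; the one-sided
variant renormalizes the prior to the positive half-line.

*Correlations.* `jeffreys_corr_bf()` integrates the exact sampling
density of Pearson's r over a stretched-beta prior on rho (default:
uniform on (-1, 1)). Only the rho-dependent kernel is evaluated — the
normalizing factors cancel in the Bayes factor — with the Gaussian
hypergeometric factor computed by direct series (the term ratio tends to
(1 + rho*r)/2 < 1, so truncation at relative 1e-14 is safe). Perfectly
collinear input (|r| = 1 to machine precision) has an unbounded
likelihood and returns an infinite BF₁₀ explicitly.

*Repeated-measures ANOVA.* `rm_anova_bf()` compares the five models of a
2x2 within design (subject-only null, +A, +B, +A+B, full) under zero-sum
±1/2 coding and scaled-g priors (scale 0.5 for fixed effects, 1.0 for
subject effects). Conditional on the batch scales g, coefficients, grand
mean (flat) and variance (Jeffreys) integrate analytically; the remaining
1-4 dimensional integral over log g is evaluated by a Laplace
approximation by default — deterministic, which the repeatability
contract requires — with optional importance-sampling refinement whose
Monte-Carlo error is reported. Inclusion BFs use matched-model averaging
with equal prior model probabilities. In null simulations the median
inclusion BF per effect sits near 0.35; a 5 SD planted effect exceeds
10^30.

## 5. The measurement-error regression

Ordinary regression of priming effects on observed awareness proportions
is attenuated by binomial noise in the predictor, which typically
inflates the intercept — the quantity of scientific interest (priming at
chance awareness). The generative model treats the true proportion
`theta_i` as latent with a Beta hierarchy centered near chance
(`mu ~ Beta(5, 5)`, concentration `~ Gamma(2, 0.05)`), and the observed
effect as the true effect plus both known per-participant sampling error
and a residual spread `tau`:

* `alpha ~ Normal(0, 50 ms)`: effects beyond ±100 ms are not plausible
  priming.
* `beta ~ Normal(0, 300 ms/unit)`: generous, since the predictor spans
  at most 0.5 units.
* `tau ~ half-Normal(0, 30 ms)`.

Bayes factors depend on these scales, so all are configurable and
reported. Sampling uses JAGS; internally the linear predictor is
reparametrized around the sample-mean awareness (the intercept at the
data's center and the slope are nearly independent there), which removes
the strong alpha-beta posterior correlation that otherwise cripples
Gibbs mixing — the declared prior on `alpha` is preserved exactly and
`alpha` is monitored as a derived node. Convergence is enforced
(max Rhat < 1.01, after at most two chain extensions with doubled
draws); non-convergence is an error, never a silent result.

BF₁₀ for `alpha != 0` is the Savage-Dickey ratio: the analytic prior
density at zero over the posterior density at zero, the latter from a
Gaussian kernel with Sheather-Jones bandwidth; a normal-approximation
estimate is reported alongside and the two are required to agree in
tests. Defaults are 4 chains x 2000 post-warmup draws; the calibration
harnesses use 2 x 1200, which keeps the posterior-mean intercept bias
under 3 ms and 95% CrI coverage near nominal across 100 simulated
cohorts of 24 participants x 256 awareness trials.

## 6. GRT-wIND and SvA curves

The joint shape x PAS data from the multiple-task and visibility blocks
are fitted to two-dimensional GRT models: one bivariate Gaussian per
stimulus class over (identity, awareness), the absent class anchored at
(0,0) with unit variances for identifiability. Individual differences
follow the wIND scheme restricted to an attention scalar `kappa_i`
multiplying present-class means (geometric mean pinned to 1; the overall
scale is absorbed into the class means after fitting, a
likelihood-invariant renormalization) plus per-participant criteria: one
identity bound (always perpendicular to the identity axis — the winning
models in this literature never relax it) and three ordered awareness
criteria. Full per-participant covariance scaling is deliberately out of
scope for tractability.

The 16 model variants are the 2^4 combinations of: equal variances (all
fixed at the absent class's units); perceptual separability (square and
diamond share the awareness marginal); perceptual independence (zero
within-class correlation); decisional separability for awareness
(horizontal bounds; otherwise all bounds share one linear slope).

**Likelihood.** With a common bound slope `s`, the decision regions are
rectangles in `(x, u = y - s x)`, which is again bivariate Gaussian, so
every cell probability is an exact bivariate-normal rectangle
probability — no 2-D quadrature. The bivariate CDF uses the
single-integral identity with 24-point Gauss-Legendre nodes (adaptive
fallback beyond |r| = 0.925), accurate to ~1e-14 against reference
implementations; cells are assembled from common CDF evaluations so each
stimulus's eight probabilities sum to 1 exactly.

**Optimization.** Parameters are transformed to an unconstrained scale
(log SDs and kappas, Fisher-z correlations, ordered cutpoints via log
gaps) and fitted by multi-start L-BFGS-B. The likelihood separates over
participants given the global parameters, so finite-difference gradients
are computed block-wise: all participants' parameters of one type are
perturbed simultaneously and each participant's own likelihood term
yields their partial derivative — about 20 likelihood evaluations per
gradient regardless of cohort size. The 16-model sweep fits the full
model first and warm-starts each constrained variant from its projection.
AIC selects among fits; exact ties go to fewer parameters, then to flag
order. Moment-based starting values come from pooled hit/false-alarm and
PAS-exceedance rates.

**Curves.** RLNA(a) is the absent/present density ratio on the awareness
axis, with the present density the equal-weight square/diamond mixture
(the design is equiprobable; empirical weighting would matter only for
unbalanced designs). Conditional d' uses the Gaussian conditional-moment
formulas with an RMS-pooled conditional SD. The ideal observer's
awareness criterion solves RLNA = 1 by bisection between the absent and
present means; when the densities never cross there, the criterion is
reported absent with a warning. Curves are evaluated on a 200-point grid
spanning [absent mean - 3 SD, max present mean + 3 SD]; refining to 2000
points moves the criterion by < 1e-3. Bootstrap bands are parametric:
simulate counts from the fitted model at the observed trial numbers,
refit the *selected* template only (warm-started), and take pointwise
2.5/97.5 percentiles; more than 20% refit failures is an error.

Fit quality is summarized as `100 * (1 - MAD / mean observed
proportion)`, where MAD is the mean absolute deviation between observed
and predicted response proportions across participants x stimuli x 8
cells; the raw MAD is reported alongside, since "percent of response
proportions accounted for" has no single established definition.

## 7. Validation scales and statistical conventions

The test suite validates, among others: the probability engine against
10^6-draw Monte-Carlo sampling for random correlated, sloped models
(cellwise 3-SE agreement with a simultaneous allowance across the 160
cells — with that many comparisons, an occasional 3-SE excursion is
expected from the oracle's own noise, so up to 1% of cells may fall
between 3 and 4.5 SE); parameter recovery and AIC selection on 20
replicate cohorts of 20 participants x 320 trials; bootstrap-band
coverage of a generating curve with 100 resamples; and the regression
calibration on 100 cohorts (plus 50 cohorts of purely awareness-driven
priming, where BF₁₀ must favor the null and the ordinary regression must
overestimate the intercept). Selection "success" counts the generating
(fully constrained) template winning outright or trailing the winner by
less than 2 AIC units: with a true model nested in every candidate,
one-parameter rivals tie it in likelihood up to sampling noise, and a
sub-2 gap is the conventional band of indistinguishable support. These
replication counts are the package's chosen validation scales; larger
runs only tighten the Monte-Carlo error around the same checks.

## 8. Known limitations

* The GRT parameterization is one defensible reconstruction of the
  wIND family; published percent-accounted figures from other toolkits
  are not directly comparable.
* The regression model is linear in centered awareness; when the true
  effect is nonlinear in `theta` (as when priming scales with a latent
  attention factor), the intercept inherits a small extrapolation bias.
* Laplace-approximate ANOVA marginal likelihoods can deviate a few
  percent from exact integration; use `method = "mc"` when the BF sits
  near a decision boundary.
* The package's own interfaces (functions plus `run_pipeline()` and the
  acceptance script) are the intended entry points; no shell CLI is
  shipped.
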