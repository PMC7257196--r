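---
title: "Regression Kriging of binary audit responses: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regression Kriging of binary audit responses: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(auditkrige)
```

This vignette is the package's account of its statistical machinery: the
models it fits, the assumptions behind them, the parameters that matter, and
the design decisions taken where the method leaves room. The README shows
the user-facing workflow; here we explain *why* each stage looks the way it
does.

## The two-stage model

Audit responses are binary (Yes = 1 / No = 2 in storage, 1/0 in analysis)
at projected planar coordinates in meters. The package assumes coordinates
arrive in an equidistant projection and never reprojects: every distance is
Euclidean in meters (kilometers internally for variography), so distance
fidelity is the caller's responsibility.

**Stage 1 — large-scale trend.** Each item is fit by maximum-likelihood
logistic regression on a centered cubic polynomial of the coordinates,
optionally plus rater dummies. Detrending serves the stationarity
assumption of the second stage: what remains should depend on relative, not
absolute, position. Two choices deserve comment:

* *The term set.* A full bivariate cubic has nine non-intercept terms; the
  default here is the seven-term set \{x, y, x², y², xy, x³, y³\}, matching
  a trend described by eight coefficients β₀–β₇. Which two cubic
  cross-terms to drop is genuinely underdetermined, so the full nine-term
  variant is available via `trend_spec(terms = "cubic9")`; nothing
  downstream depends on the choice.
* *Conditioning.* Coordinates are centered at their means and expressed in
  kilometers before the polynomial expansion. Cubics of meter-scale
  coordinates reach 10¹² and defeat the IRLS solver; on centered kilometer
  coordinates the design is well-conditioned without further scaling.
  Centering constants are stored on the model and reused verbatim at
  scoring time.

Rater adjustment uses dummy coding with the *last* rater level as the
reference; the fitted level order is stored on the model and reused when
scoring, so the mapping between coefficients and raters can never drift
between fitting and prediction. Scoring at a rater level the model has not
seen raises an error unless the caller opts into the reference-level
fallback (the sensible choice when predicting at unaudited locations with
no rater at all).

**Stage 2 — small-scale residual structure.** The deviance residual
ε = sign(y − p̂) · √(−2[y ln p̂ + (1 − y) ln(1 − p̂)]), with p̂ clamped to
[10⁻¹², 1 − 10⁻¹²], is treated as a stationary spatial field: estimated by
semivariography, modeled by nested theoretical semivariograms, and
predicted at held-out locations by local ordinary Kriging.

## Variography

The empirical semivariogram is the Matheron estimator on equal-width
distance bins — 40 bins to half the maximum pairwise distance by default.
Those defaults are package choices (the analysis they mirror does not
publish its lag configuration) and are exposed via `n_lags`, `lag_width`,
`max_lag`. Directional variograms use eight axes at 22.5° spacing with a
±11.25° tolerance, which partitions every point pair into exactly one
direction. Empty bins are kept with `np = 0` and excluded from fitting.

Fitted models are a nugget plus one or two structures from \{spherical,
exponential, Gaussian, Matérn, cubic, sine-hole, power\}. Conventions:

* spherical and cubic reach their partial sill exactly at the range;
* exponential, Gaussian and Matérn use the scale-parameter convention
  γ(h) = c(1 − ρ(h/a)) and approach the sill asymptotically (the
  exponential's practical range is ≈ 3a);
* the sine-hole (wave) model is γ(h) = c[1 − sin(πh/a)/(πh/a)] — the
  parameterization is stated explicitly because hole-effect conventions
  differ across software;
* the power model γ(h) = b·hᵖ, p ∈ (0, 2], has no sill, which is why the
  Kriging solver works in the semivariogram formulation throughout (a
  covariance formulation would exclude power structures).

Fitting minimizes the Cressie weighted SSE, Σ N(h)[γ̂(h) − γ(h)]²/γ(h)²,
with `nlminb` under box constraints (partial sills ≥ 0, ranges ≥ 10⁻⁶ km —
the lower bound visible in published boundary estimates — and p ≤ 2). The
WLS surface is multimodal, so each candidate runs from a deterministic grid
of ~12 starts (method-of-moments sill/nugget estimates crossed with short,
medium and long initial ranges and two sill splits); Matérn smoothness is
profiled over \{0.5, 1, 1.5, 2.5\}. The best model over all candidates wins
on weighted SSE with ties broken toward fewer parameters, and the full
candidate ledger is attached to the result. Fitting requires at least five
non-empty bins.

### Anisotropy classification

The published analysis judged anisotropy visually. A quantitative surrogate
needs care: directional fits on a single realization fluctuate far more
than intuition suggests, and comparing each direction to the
omnidirectional curve halves the signal because the omnidirectional curve
is essentially the directional average. The package therefore summarizes
each directional model by its mean semivariance (as a fraction of the
omnidirectional sill) over the structured lag zone, and computes the
amplitude of the *second circular harmonic* of these eight levels —
geometric anisotropy has exactly this 180°-periodic signature, while
direction-balanced noise largely cancels in the projection. The amplitude
is computed both within the omnidirectional effective range and over the
full structured zone: small in both → `None`; small within range but large
beyond → `>= Mid-range`; large within range → `Yes`, reporting the axis of
maximum continuity. The default tolerance (0.06 of the sill) was calibrated
by simulation: isotropic fields at desk-scale sampling stay below ~0.04,
3:1 range anisotropy sits near or above ~0.09. It is a package-defined
surrogate for a qualitative judgment and is exposed as `tol`.

## Local ordinary Kriging

Neighborhoods follow the radius-or-minimum rule: all training points within
1.3 km, expanded to the nearest 30 when fewer fall inside (both
configurable via `kriging_plan()`). The OK system is solved in
semivariogram form with a Lagrange multiplier; weights sum to one by
construction, predictions are Σ wᵢεᵢ, and the Kriging variance is
w'γ₀ + μ (floored at zero against roundoff). Co-located training points are
averaged before solving — duplicated coordinates make the system singular —
and a least-squares pseudo-solve backs up the direct solve near
singularity. Exactness at data locations holds when the nugget is zero;
with a pure-nugget model the predictor collapses to the neighbor mean, the
correct limiting behavior.

## Back-transformation

The analysis being mirrored sums a kriged *deviance-scale* residual into a
probability, which requires inverting the deviance residual at a given
trend probability — an operation it does not specify. The naive route,
substituting a fractional pseudo-response u into the binary formula
sign(u − p̂)√(−2[u ln p̂ + (1 − u) ln(1 − p̂)]), is unusable: that function
is discontinuous at u = p̂ (it jumps between ±√(2H(p̂))) and non-monotone
for p̂ > ½, so it has no well-defined inverse. The package instead inverts
the standard continuous binomial deviance

d(u, p̂) = sign(u − p̂) · √(2[u ln(u/p̂) + (1 − u) ln((1 − u)/(1 − p̂))]),

which coincides with the binary formula exactly at u ∈ \{0, 1\}, is
continuous, zero at u = p̂, and strictly monotone — so binary observations
round-trip exactly. Inversion is by bisection to 10⁻¹⁰ after clamping the
kriged value to the attainable interval [d(0, p̂), d(1, p̂)] (equivalently
|r*| ≤ max(p̂, 1 − p̂)). An `"identity"` mode that passes the kriged value
straight through on the residual scale is provided for sensitivity
analysis. Assembled predictions p̂ + r* are clipped to [0, 1].

## Evaluation

RMSPE is computed against the 0/1 validation responses; ROC AUC is the
Mann–Whitney concordance with ties counted ½, computed from rank sums (and
cross-checked against both exhaustive pair enumeration and `pROC` in the
tests). Percent changes are 100(after − before)/before. Accuracy labels
follow the half-open taxonomy: exactly 0.5 `None`, [0.7, 0.8) `Acceptable`,
[0.8, 0.9) `Excellent`, ≥ 0.9 `Outstanding`, anything else below 0.7 `less
than Acceptable`. `summarize_results_table()` computes the headline counts
of a 31-item × 2-variant table; its group means accept an item-exclusion
list because a single extreme item can dominate a 10-item group mean.

The train–validation split is one uniform 90–10 draw per item, shared by
the rater and no-rater variants so their comparison is paired; it is not
stratified by response (rare items can in principle lose a class in the
validation draw, which surfaces as a recorded failure rather than a crash).

## The synthetic-data generator

The generator exists because the audited dataset is not public. It emulates
the *statistical structure* the analysis assumes, as a logistic
Gaussian-random-field model run in reverse:

* **Locations.** Uniform proposals thinned by a minimum-separation
  (hard-core) rule on a grid hash, with the separation adapted
  multiplicatively (from 0.6 × target, by the ratio target/achieved) until
  the mean nearest-neighbor distance lands within one stated SD (18 m) of
  the 150 m target — the sampling scheme's published stopping criterion.
  The default point budget is 25.3 points/km², the study's density. The
  initial separation comes from a Matérn-II approximation of hard-core
  mean NN distance at that density, not from tuning.
* **Latent field.** A zero-mean Gaussian field with covariance
  C(h) = sill − γ(h) for a nested model, drawn by dense Cholesky with 10⁻⁸
  jitter and a documented cap of 5,000 points (exactness over scalability;
  the cap covers every problem size used here). Sine-hole and power
  structures are refused in the generator — hole-effect covariances are not
  positive definite in the plane for all parameters and the power model has
  no sill — although both remain available to the *fitting* side.
* **Responses.** P(Yes) = logistic(cubic trend + rater offset + field),
  Bernoulli-sampled and stored in 1/2 coding; an optional prevalence target
  re-solves the intercept by `uniroot`. Raters default to four, assigned at
  random. Default rater offsets are (+0.5, 0, −0.5, 0) logits.
* **Default latent model.** Nugget 0.1 + exponential(psill 1.5, scale
  0.8 km) + spherical(psill 0.8, range 4 km) on the logit scale — a
  two-scale structure whose consequences (full-model AUCs around 0.7–0.8,
  Kriging AUC gains of roughly 5–70% relative) fall inside the published
  ranges of the study being emulated. This is calibrated emulation of
  printed outcomes, chosen once; it is an assumption about a data-generating
  process the study itself cannot reveal.
* **Block groups.** Exact rectangular-band tilings of the extent (no
  polygon machinery is needed for synthetic census geography), with
  covariates drawn as ρ·z + √(1 − ρ²)·noise against the standardized
  unit-mean latent field, so configured correlations are recovered in
  expectation. Defaults mimic racial-ethnic composition, mobility, housing
  value and density variables in plausible units, without truncation (a
  clamped percentage would distort the configured correlations, which the
  tests rely on).

What passing tests on this generator do **not** show: road-network
geometry (points lie on a featureless plane), rater assignment by item
group, spatio-temporal imagery effects, or any real-data misfit between the
logistic-GRF assumption and actual audit behavior.

All randomness flows from a single master seed through tagged sub-streams
(`derive_seed`), so stages are individually reproducible and mutually
independent.

## Probability surfaces and block-group correlations

Surfaces are Nadaraya–Watson ratios under an isotropic Gaussian kernel on a
regular grid; cells whose total kernel weight falls below a threshold
(default 10⁻³) report the overall prevalence rather than a 0/0 artifact.
The bandwidth minimizes the leave-one-out Bernoulli negative log-likelihood
over a candidate grid (default: 16 log-spaced values from the mean
nearest-neighbor distance to a quarter of the extent diagonal), with
probabilities clipped to [10⁻⁶, 1 − 10⁻⁶] inside the likelihood and ties
resolved toward the smaller bandwidth. Rendering uses a divergent palette
whose white midpoint is the item prevalence.

Block-group correlations treat the k = 10 predicted values per unit as
imputations: per-imputation Pearson correlations across units are pooled by
Rubin's rules on the Fisher-z scale (within-imputation variance 1/(n − 3),
total = within + (1 + 1/m) · between), then back-transformed. The Fisher
scale is used because Rubin's rules assume approximate normality, which
raw correlations near ±1 violate. When scoring at unaudited block-group
points, the rater term is evaluated at the reference level.

## Problem sizes and numerical tolerances

The test suite and acceptance script run at desk scale by design: synthetic
items of 900–2,000 points, 15–40 variogram bins, 5–12 seeded replicates per
property, and a 30 km²–330 km² extent for the location sampler. Parameter
recovery for WLS variography is asserted on the median over five seeds
because single-realization nugget and range estimates routinely wander
beyond ±25% even at n = 2,000 — an honest property of the estimator, not of
the implementation. Numerical tolerances that matter: probability clamp
10⁻¹² (deviance), 10⁻⁶ (CV likelihood); bisection to 10⁻¹⁰; Cholesky jitter
10⁻⁸; Kriging weight-sum identity to 10⁻⁹; range lower bound 10⁻⁶ km.

## Known limitations

* Ordinary Kriging of deviance residuals is an ad hoc composite — the
  residuals of a logistic fit are neither Gaussian nor exactly stationary,
  and no frequentist universal-Kriging theory exists for binary data. The
  package implements the composite faithfully rather than repairing it.
* The back-transformation is this package's interpretation (documented
  above); alternatives would change RMSPE more than AUC, since AUC is
  invariant to monotone transforms.
* The anisotropy classifier trades the published visual judgment for a
  calibrated statistic; labels near the tolerance boundary should be read
  as genuinely ambiguous.
* Dense Cholesky caps generated fields at 5,000 points; larger synthetic
  studies would need a different simulator (circulant embedding, turning
  bands) that is out of scope here.
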