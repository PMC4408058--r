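---
title: "Methods: from camera traps to functional responses of human predation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from camera traps to functional responses of human predation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(predresp)
```

This vignette documents the models implemented in `predresp`, the
assumptions they make, the synthetic world the generator states, and the
numerical choices that a user fitting real data should know about.

## 1. Density from camera trapping: spatially explicit capture–recapture

Camera-trap surveys of individually identifiable carnivores yield binary
detection histories: which animal was photographed at which camera on
which day. SECR treats each animal as anchored to a latent *activity
centre* `s` and models detection at a camera a distance `d` away with the
half-normal function

    p(d) = g0 · exp(−d² / (2σ²)),

where `g0` is the detection probability at the centre and `σ` (km) the
spatial scale of decline. Assumptions inherited from the model family:
the activity centre is fixed for the survey (demographic and geographic
closure — the rotating-block design should stay within ~90 days), home
ranges are circular, and detections are independent Bernoulli trials per
(occasion, detector). We use *binary proximity detectors*: an animal can
be photographed at several cameras on one occasion, but at most once per
camera per occasion. Cameras that were not running on an occasion are
recorded in a usage matrix and contribute nothing.

Because body size and ranging differ strongly between the sexes in large
felids, `g0` and `σ` are sex-specific by default (`fit_secr(...,
sex_specific = TRUE)`); every captured individual must therefore have a
known sex — an unsexed record is an error, not a latent class.

The likelihood is *conditional on capture*: with `ω_i` the history of
individual `i` and `p·(s)` the probability of at least one detection for
a centre at `s`,

    logL = Σ_i log [ Σ_s Pr(ω_i | s) Δ ] − log [ Σ_s p·(s) Δ ],

integrated numerically over a habitat mask — a lattice of candidate
centres covering the detectors plus a buffer — with cell area `Δ`
(which cancels, as one of the test invariants asserts). Density follows
by Horvitz–Thompson: each captured animal contributes the inverse of its
sex's *effective sampling area* `a = Σ_s p·(s) Δ`, and
`D = Σ_i 1/a_{sex(i)}`, scaled to animals per 100 km².

Numerical choices:

* Optimisation is on the transformed scale (logit `g0`, log `σ`) by
  quasi-Newton (BFGS, finite-difference gradients), relative tolerance
  `1e-8` on the log-likelihood, with a Nelder–Mead fallback.
* Mask defaults: buffer `4 × σ₀` where `σ₀` is half the maximum distance
  between detectors at which one individual was recorded (falling back to
  half the median camera spacing when nobody moved); spacing
  `buffer/16`. Both are overridable; halving the default spacing changes
  density by well under 1% in our tests, and a buffer beyond `4σ` adds
  essentially nothing because `p·` has decayed to numerical zero.
* The SE of `D` combines the Horvitz–Thompson sampling term
  `Σ 1/a_i²` with a delta-method term using the inverse Hessian of the
  negative log-likelihood. In 200-replicate simulations at
  `D = 5/100 km²`, `g0 = 0.15`, `σ = 1.5 km` the nominal 95% interval
  covers ~88% — acceptable for an estimator that ignores the covariance
  between individual detection and parameter estimation.
* A survey with no spatial recaptures and a single used camera leaves
  `σ` unidentifiable; `fit_secr()` flags the fit `converged = FALSE`
  (`degenerate = TRUE`) rather than returning a confident number.

## 2. From site densities to a regional abundance surface

The habitat input is a gridded logistic suitability score `hs ∈ [0, 1]`
(10 km² pixels by default) from an upstream presence-only distribution
model; training that model is out of scope and any raster of logistic
scores will do. Each camera-trap site's density is spread uniformly over
its pixels (`a = D · pixel_area / 100` animals per pixel) — the survey
data cannot resolve within-site variation, and this choice is flagged in
the output rather than hidden. The expected abundance of one
*ideal-habitat* pixel is the two-stage average

    A = (1/K) Σ_i (1/n_i) Σ_j a_ij / hs_ij ,

and the regional surface is `a′ = A · hs` per pixel, so the expected
count in any region is the sum of `a′` over the pixels whose centres fall
inside it. A pixel with `hs = 0` inside a site footprint is a
contradiction (animals were observed where the habitat model says none
can be) and raises an error naming the pixel. The SE of `A` treats the
within-site pixel terms as perfectly correlated (they share one density
estimate) and sites as independent — a delta-method choice; the
uncertainty of the suitability model itself is not propagated.

## 3. The analysis grid

Kill records and abundance meet on a coarse grid of nominal 2,500 km²
square cells (the scale of the permit-administration units the analysis
mirrors), clipped to the region outline. The grid origin is the
bounding-box lower-left corner; it carries no information and can be
shifted for sensitivity analysis. Cells cropped below half the nominal
size would be noisy after rescaling, so any cell under 1,250 km² is
merged into the adjacent cell sharing the longest clipped boundary (ties
to the lower cell id), smallest first, until all pass; total area is
conserved exactly and an isolated fragment with no positive shared
boundary is an error rather than a silent drop.

Kills are assigned by point-in-cell with half-open edges (a point on a
shared edge belongs to the lower-indexed cell, never to both); each
record is one death at one point — upstream georeferencing to farm
centroids is taken as given, and a record outside every cell is excluded
and counted in the log, never silently. Finally both abundance and kill
counts are rescaled by `2500 / raw_area` to full-cell equivalents, which
preserves per-km² rates and leaves full cells untouched; scaled counts
may be fractional and enter the regression as such.

## 4. Functional responses and model selection

Three response forms relate kills per full cell to expected abundance
`N`: linear (type I, `y = a + bN`, the opportunist), hyperbolic
(type II, `y = kN/(x+N)`, the specialist, saturating at `k` with
half-saturation at `x`), and sigmoidal (type III,
`y = kN^r/(x^r+N^r)`, the generalist; `r = 1` recovers type II exactly,
so type III can never fit worse — a nesting the tests assert on every
dataset). The type I intercept is retained even though it permits
negative predicted kills at low abundance; predictions are reported
as-is, not truncated.

Fitting is unweighted Gaussian least squares: type I in closed form,
types II and III by an in-package Levenberg–Marquardt solver on the log
scale of `(k, x, r)` with central-difference Jacobians, step clamping,
and multiple starts (`k₀ = 2·max(kills)`, `x₀ = median(N)`,
`r₀ ∈ {1, 2, 8}` — the high start matters when the true response is
nearly a step). Standard errors come from the Jacobian at the optimum,
`s²(JᵀJ)⁻¹`; for a saturating curve with no saturation in the data these
blow up into the astronomically wide intervals familiar from published
kill-rate tables, which is the honest answer.

Support is judged by AICc with the error variance counted as a
parameter (`p = curve parameters + 1`):

    AICc = n log(rss/n) + 2p + 2p(p+1)/(n − p − 1),

and all models within 2 AICc units of the best are reported as the
*equal-support set*. An exact interpolation (`rss = 0`) has no defined
AICc; the fit is flagged `perfect_fit` and treated as `−Inf` (it wins).
Residual diagnostics report standardised residuals, flag `|z| > 3`, and
attach a Shapiro–Wilk summary; nothing is ever dropped automatically.

## 5. The synthetic world

The generator's defaults state one fixed world, chosen once:

* Region: a smooth random outline of radius ~126 km (≈ 50,000 km², the
  scale of the district the method targets), 10 km² pixels.
* Suitability: white noise smoothed by repeated local averaging,
  rescaled to `[0.05, 1]` — spatially autocorrelated (lag-1 correlation
  > 0.5), never exactly zero, bit-reproducible per seed.
* Abundance truth `A* = 1.06` animals per ideal pixel, matching the
  magnitude a leopard analysis reports; placement is inhomogeneous
  Poisson with a fair sex ratio.
* Surveys: 3 blocks × 14 cameras × 20 days (within the 13–15 cells and
  18–21 days of the rotation it emulates; 60 days total, inside the
  90-day closure comfort zone), cameras 2.5 km apart, `g0 = 0.15`,
  `σ = 1.5 km` for both sexes.
* Kills: `max(0, predict(truth, N) + Normal(0, 2))` per cell, with a
  sigmoidal retaliatory truth (`k = 13`, `x = 67`, `r = 12`) and a
  linear sport-hunting truth (`a = −5`, `b = 0.14`) of published-table
  magnitude, truncation events logged.

What a green test does and does not establish: the generator realises
exactly the model the fitters assume (static centres, independent
Bernoulli detections, Gaussian kill noise). Recovery there validates the
estimators' implementation, not their robustness to transients, animal
movement, unmodelled detector covariates (film vs digital cameras, say)
or overdispersed counts — none of which the synthetic world contains.
One consequence worth spelling out: with the linear truth `a = −5` the
zero-truncation makes the generated data *sigmoidal* wherever the linear
predictor is negative, and a selection experiment run across low
abundances then correctly prefers type III — a property of the truncated
generator, not an error of the fitter. The model-selection experiments
therefore use abundances where the linear predictor clears five noise
standard deviations, which provably never truncates; under that honest
linear generator the true form stays in the equal-support set in ~98% of
replicates.

## 6. Design decisions taken where the design was open

* One day = one occasion in the synthetic survey protocol; occasion
  aggregation is a property of the data, not the likelihood.
* Sites are fitted separately, not pooled in one model with shared
  parameters.
* Raster I/O is restricted to the plain-text ESRI ASCII grid dialect —
  the deliverable carries no binary formats and no geodesy; coordinates
  are projected kilometres throughout.
* Kill assignment uses the record point, with no areal apportionment of
  a farm that might straddle two cells; the half-open tie-break makes
  the assignment deterministic.
* Published AICc tables rounded to two decimals reproduce their support
  sets but not their delta values to the last digit; deltas are always
  recomputed from unrounded internals and never chased against rounding.

## 7. Known limitations

Conditional-likelihood SECR only (no full likelihood, no density
surfaces, no open populations); no mixture handling for unsexed animals;
no Poisson/negative-binomial alternative for kill counts (the Gaussian
choice mirrors the least-squares fitting convention of the analyses this
package reimplements); polygon handling assumes planar, already
projected coordinates and modest vertex counts.
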