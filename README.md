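# predresp

Tools for asking how human predation on large carnivores responds to
carnivore abundance. The package implements a complete inference chain for
regional kill-rate analyses of the kind used for leopard (*Panthera
pardus*) populations subject to retaliatory killing and recreational
trophy hunting:

1. **Density from camera traps (SECR).** Maximum-likelihood spatially
   explicit capture–recapture with a half-normal detection function
   `p(d) = g0 · exp(−d²/2σ²)`, binary proximity detectors, per-occasion
   usage matrices for rotating camera blocks, and detection parameters
   (`g0`, `σ`) free to differ by sex. The likelihood is conditional on
   capture; density is the Horvitz–Thompson sum `D = Σᵢ 1/aᵢ` of inverse
   effective sampling areas, reported per 100 km².
2. **Abundance extrapolation.** Site densities are spread over the pixels
   of a habitat-suitability raster and deflated by the logistic
   suitability score to estimate the expected abundance of one
   ideal-habitat pixel, `A = (1/K) Σᵢ (1/nᵢ) Σⱼ aᵢⱼ/hsᵢⱼ`; the abundance
   surface is then `a′ = A · hs`, summable over any region of interest.
3. **Spatial aggregation.** A nominal 2,500 km² analysis grid is clipped
   to the region, undersized border cells (< 1,250 km²) are merged into
   the neighbour with the longest shared boundary, kill records are
   counted into cells by point location, and cropped cells are rescaled
   to full-cell equivalents.
4. **Functional responses.** Per-cell kills versus abundance are fitted
   with Holling type I (`y = a + bN`), type II (`y = kN/(x+N)`) and
   type III (`y = kN^r/(x^r+N^r)`) curves by Levenberg–Marquardt least
   squares, compared by small-sample corrected AIC (AICc), with models
   within 2 AICc units treated as equally supported.

A synthetic-data module generates every input — suitability surfaces,
activity centres, rotating-block surveys, capture histories, kill
records — so the whole chain is testable without field data.

## Worked example

```r
library(predresp)

report <- run_pipeline(sim_config(seed = 1))
report
#> <pipeline_report>
#>   site L: D = 6.58 per 100 km^2 (SE 1.39), n = 23
#>   site W: D = 8.99 per 100 km^2 (SE 1.61), n = 32
#>   site M: D = 8.35 per 100 km^2 (SE 1.52), n = 31
#>   ideal-pixel abundance A = 1.058 (SE 0.116)
#>   total expected abundance: 3209 animals
#>   analysis cells: 20 (raw area 1450-3776 km^2)
#>   retaliatory equal-support set: {I, II}
#>   hunt equal-support set: {III, I, II}
```

Each site line is a SECR fit: estimated leopards per 100 km² with its
standard error and the number of distinct individuals photographed. `A`
is the expected number of animals in a single 10 km² pixel of perfect
habitat, recovered here within half a percent of the generating truth
(1.06). The equal-support sets list the response forms within 2 AICc
units of the best fit for each mortality cause; with the default noisy
generator several forms are often indistinguishable, exactly as with
real kill-permit data.

Individual stages are ordinary functions on tibbles:

```r
fit <- fit_secr(read_captures("caps.csv", read_detectors("traps.csv")))
tidy(fit)      # per-sex g0 and sigma with SEs
glance(fit)    # density, SE, log-likelihood

cmp <- compare_models(lapply(c("I", "II", "III"), fit_model, data = cells))
equal_support(cmp)
autoplot(cmp)  # data + fitted curves
```

## Acceptance script

`scripts/acceptance.R` re-runs the full synthetic pipeline from scratch
against the installed package and writes its JSON summary:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Vignette

`vignettes/methods.Rmd` describes the models, their assumptions, the
synthetic world the generator states, and the numerical choices
(optimiser scales, tolerances, tie-breaks, degenerate designs).
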