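---
title: "Allelic manifolds: models, inference and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allelic manifolds: models, inference and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allelic)
```

## The measurement geometry

A bacterial promoter is modeled as an equilibrium over a handful of
occupancy states, each with a Boltzmann weight and a transcript
initiation rate. Two dimensionless binding factors set the weights: `P`
for RNAP and `F` for the regulating TF, each expressible as
concentration times affinity or as `exp(-ΔG/kBT)`. Measuring each
promoter variant twice — transcription with the TF active (`t+`) and
inactive (`t-`) — yields a point in a two-dimensional space. Across an
allelic series of RNAP-site variants only `P` changes, so the points
sweep a one-dimensional curve. The shape of that curve, not the
(unknown) `P` of any individual variant, carries the regulatory
energetics:

* **repression** (TF occludes RNAP): `t+ = tsat·P/(1+F+P) + tbg`,
  offset `1+F` below the diagonal in its parallel regime;
* **stabilization** (cooperativity `α` on the doubly bound state):
  `t+ = tsat·α'P/(1+α'P) + tbg` with `α' = (1+αF)/(1+F)`;
* **acceleration** (the ternary complex initiates `β`-fold faster):
  `t+ = β'·tsat·α'P/(1+α'P) + tbg` with `β' = (1+αβF)/(1+αF)`.

The unregulated channel is always `t- = tsat·P/(1+P) + tbg`. The
`form = "states"` and `form = "renormalized"` arguments of the rate
functions evaluate the explicit state-sum and the collapsed expressions;
they are algebraically identical and the test suite holds them to 1e-12
relative agreement on random parameter grids, with an independent
brute-force state enumeration as the oracle.

Free energies are reported in kcal/mol using the fixed conversion
1 kcal/mol = 1.62 kBT at 37 °C (`kbt_convention()`), i.e. natural-log
conversion `ΔG = -kBT·ln(x)`. The physically derived value at 310.15 K
(`kbt_kcal()`, 0.6165 kcal/mol) differs from the convention (0.6173) by
0.1%; the fixed convention is used for reporting so that two-decimal
ΔG values are stable and reproducible.

## Regimes

With `F ≫ 1` (repression) or `tsat/tbg ≫ α'β' > 1` (activation) the
manifold decomposes into five asymptotic regimes: background-dominated,
single-channel proportional, parallel offset, singly saturated, doubly
saturated. The boundaries implemented in `regime_boundaries()` are the
crossover points where adjacent dominant terms of the exact expressions
intersect — for repression `tbg/tsat`, `(1+F)·tbg/tsat`, `1`, `1+F`; for
activation `tbg/(α'β'·tsat)`, `tbg/tsat`, `1/α'`, `1`. These follow from
dominant-term analysis and are stated next to the formulas in the code;
they tile `(0, ∞)` without gaps. When the validity conditions fail the
package raises a typed `regimes_undefined` error rather than returning a
silently wrong label. A `strictness` factor shrinks each regime about
its log-midpoint for conservative classification near boundaries
(default 1: exact tiling). At regime midpoints at least two decades
deep, the approximate expressions agree with the exact rates to better
than 15%, improving with dynamic range `tsat/tbg` in the regime whose
depth grows with it.

## Fitting

`fit_manifold()` minimizes squared residuals of `log10` rates against
the model, jointly over the shared parameters and one `P_i` per
promoter (n+3 or n+4 parameters for 2n measurements; at least one more
measurement than parameters is enforced). Choices that matter:

* **Log-space loss.** Measurements span more than four decades and
  replicate noise is multiplicative, so residuals are taken on log10
  rates. The residual function is isolated (`manifold_residuals()`) so
  a different weighting could be substituted in one place.
* **Log-parameterization.** Every positive parameter is optimized as
  its logarithm — positivity by construction, and scale-free steps for
  the Levenberg-Marquardt solver (`minpack.lm::nls.lm`, ftol = ptol =
  1e-15, up to 1000 iterations).
* **Initialization and multistart.** `tbg` starts below the smallest
  measurement, `tsat` above the largest; `F` (or `α'`) from the median
  `t-/t+` (or `t+/t-`) ratio; each `P_i` by inverting the `t-` equation
  at the initial `(tsat, tbg)`, clipped away from the background and
  saturation limits. Additional starts (default 10) perturb the shared
  parameters log-uniformly within one decade under a seeded stream;
  the best converged loss wins, ties broken by start order. On
  noiseless data the fit returns the generating parameters to machine
  precision.
* **Renormalized parameterization.** Only `α'` (and `β'`) are visible
  in the manifold; `α` and `β` are recovered by inverting their
  renormalization at a separately measured TF binding factor `F_tf`,
  exactly as the class I analysis converts its fitted `α'` using the
  occlusion-derived `F`. With `F_tf = Inf` (default) the reported `α`
  *is* `α'`, the `F ≫ 1` limit.

### Identifiability

Two structural facts shape the interface. First, `α` and `F` cannot be
separated by a single activation manifold — only their combination
`α'` — which is why `F_tf` enters as a known constant. Second, the
acceleration model with free `tsat` is degenerate: substituting
`s = t- - tbg` gives `t+ - tbg = A·s/(1+B·s)` with `A = α'β'` and
`B = (α'-1)/tsat`, so `(tsat, α', β')` influence the curve only through
`(A, B)` and a noiseless fit can land anywhere on a zero-loss ridge.
`A`, `B` and `tbg` are still recovered exactly. This is why `fit_beta()`
requires a fixed `tsat`, determined beforehand — in practice by
`joint_fit()`, which shares a single `tsat` across architectures, at
least one of which must reach saturation. `fit_beta()` additionally
warns when no inferred `P` reaches 0.1, where `β` is weakly identified
for lack of near-saturated points.

### Uncertainty, outliers, titration

`bootstrap_manifold()` resamples promoters — the `(t-, t+)` pair is the
exchangeable unit — with replacement, refits each replicate starting
from the point estimate, and reports percentile intervals (16/84 for
68%, 2.5/97.5 for 95%). Replicate-level resampling is not modeled, as
the replicate error structure of real assays is dominated by
promoter-level deviations. Failed replicate fits are dropped and
counted; more than 20% failures aborts.

`detect_outliers()` guards against promoter variants whose mutations do
more than change `P`. A soft-L1 robust preliminary fit (IRLS, transition
scale 0.1 decades) prevents gross outliers from dragging the estimate.
Flagging residuals are anchored on the unregulated channel: `P` is read
off by inverting the `t-` equation, so a promoter whose *regulation*
deviates shows its full deviation in the `t+` residual instead of
splitting it between channels through the free `P_i`. Rows exceeding
0.5 decades (about 3.2-fold; configurable) on the worse channel are
flagged, reported, and excluded only on an explicit refit. If more than
25% of rows would be flagged the model has failed to collapse the data
to a manifold at all — a two-dimensional scatter, which some promoter
architectures genuinely produce — and a typed `collapse_failure` error
is raised instead.

`titration_fit()` handles effector titrations: each concentration's
manifold is fit with `(tsat, tbg)` fixed and only `F` (plus nuisance
`P_i`) free, and the power-law dependence of `F` on concentration is
summarized by OLS on `log F` vs `log c` over the largest four
concentrations (configurable) — the smaller ones carry large asymmetric
uncertainties — with a 95% confidence interval from the regression.

## The synthetic-data generator

`simulate_allelic_series()` emulates the statistical structure the
analysis assumes: an allelic series with `P` log-uniform (or log-spaced)
over `[1e-4, 3]` by default — populating the background through singly
saturated regimes as real RNAP-site mutagenesis does; reaching the
doubly saturated regime, needed to identify `β`, requires widening the
range deliberately — forward-evaluated through the exact rate equations
at defaults `tsat = 15.1` a.u., `tbg = 0.0023` a.u., `F = 23.9`,
`α = 712`, matching the scale of the measured systems. Noise is
multiplicative and independent per row and channel:
`observed = model × exp(ε)`, `ε ~ N(0, ln(1+CV))`, default CV 10%.
Outliers multiply `t+` only (new TF sites perturb regulation, not the
RNAP-only channel) by a log-uniform factor within ±1 decade but outside
`(0.5, 2)`, so they are distinguishable from replicate noise.
`simulate_titration()` adds `F(c) = F_ref·(c/c_ref)^exponent` over seven
concentrations spanning 2.5-250 (µM scale), `t-` independent of `c`.

What the generator does *not* emulate: promoter-to-promoter variation
in `tbg` (the model fits a single `tbg` per architecture, and real data
show residual structure in the background regimes), replicate-level
error correlations, and any sequence-level structure mapping binding
sites to `P`. Passing tests on synthetic data therefore demonstrate
correctness of the inference machinery under the stated noise model,
not robustness to these real-data features.

## Problem sizes and numerical conventions

The validation suite runs at desk scale, chosen to exercise every
regime of each analysis: recovery tests use 12-20 promoters; the
precision study uses 200 independent datasets of 40 promoters spanning
the background-proportional through singly saturated regimes with 100
bootstrap replicates each (bootstrap refits start from the point
estimate with a single start, which is what makes this tractable);
acceleration discrimination uses 20-promoter series reaching `P = 100`.
All randomness flows from explicit integer seeds; the same seed
reproduces tables, ensembles and serialized JSON byte-for-byte. JSON
summaries are versioned and serialized at 12 significant digits.

```{r example}
sim <- simulate_allelic_series(16, "stabilization", noise_cv = 0,
                               P_spacing = "log-spaced", seed = 1)
fit <- fit_manifold(sim$data, "stabilization", F_tf = 23.9, n_starts = 2)
round(c(fit$estimates[c("tsat", "alpha")], dg_alpha = fit$dg$dg_alpha), 3)
```

## Known limitations

* Errors-in-variables geometry is not modeled: both channels are noisy,
  but residuals are attributed per channel, not orthogonally to the
  manifold.
* The regime boundaries are dominant-term crossovers; other conventions
  shift labels near boundaries (use `strictness` to be conservative).
* `tbg` is one value per architecture; structured residuals in regimes
  1-2 are expected when that assumption fails.
* Percentile bootstrap intervals on 100 replicates are accurate to a
  few percent in coverage; the suite verifies 68% intervals cover at
  their nominal rate within ±7%.
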