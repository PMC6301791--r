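# allelic

Thermodynamic dissection of cis-regulatory energetics from paired
reporter measurements, via **allelic manifolds**.

## The problem

How strongly does a transcription factor (TF) bind its site in a living
cell, and how strongly does it interact with RNA polymerase (RNAP) once
both are bound? In vitro affinities often miss in vivo reality by orders
of magnitude. A clean in vivo route is to measure transcription from a
*series of promoter variants that differ only in their RNAP binding
site* ("allelic series"), each assayed twice: with the TF active
(`t+`) and inactive (`t-`). Plotted against each other on log-log axes,
these paired measurements collapse onto a one-dimensional curve — the
allelic manifold — whose geometry encodes the regulatory energetics
while the unknown RNAP-DNA binding strength of each variant only moves
points *along* the curve.

## The models

Promoter states carry Boltzmann weights built from dimensionless binding
factors: `F = [TF]·K_F` for the TF, `P = [RNAP]·K_P` for RNAP, with
`F = exp(-ΔG_F / k_B T)` and similarly for `P`. Transcription is the
weight-averaged initiation rate over states plus a background `tbg`:

- **No TF:** `t- = tsat · P/(1+P) + tbg`
- **Simple repression** (TF occludes RNAP):
  `t+ = tsat · P/(1+F+P) + tbg` — the manifold runs parallel to the
  diagonal, offset below it by `1+F`.
- **Activation by stabilization** (TF-RNAP cooperativity α):
  `t+ = tsat · α'P/(1+α'P) + tbg` with `α' = (1+αF)/(1+F)` — offset
  *above* the diagonal by `α'`.
- **Acceleration** (the ternary complex initiates β-fold faster):
  `t+ = β'·tsat · α'P/(1+α'P) + tbg` with `β' = (1+αβF)/(1+αF)` — the
  manifold saturates β'-fold above the diagonal, which is the fingerprint
  separating acceleration from pure stabilization.

Fitting n promoters involves n+3 (or n+4) parameters against 2n
log-rate measurements: the shared `(tsat, tbg, F or α[, β])` plus one
nuisance `P_i` per promoter. The package does this by multistart
Levenberg-Marquardt on log-parameters, flags outlier promoters against a
robust (soft-L1) preliminary fit, quantifies uncertainty by bootstrap
resampling of promoters, classifies manifold points into the five
asymptotic regimes, and converts factors to Gibbs free energies in
kcal/mol (1 kcal/mol = 1.62 k_B T at 37 °C). A seeded synthetic-data
generator reproduces the statistical structure of the assays (log-spaced
allelic series, multiplicative replicate noise, occasional outliers, an
effector titration with a power-law TF response) so the entire pipeline
is testable end to end.

## Worked example

```r
library(allelic)

# an occlusion-architecture allelic series: 41 promoters, 10% replicate
# noise, a couple of outliers
sim <- simulate_allelic_series(41, "repression", noise_cv = 0.1,
                               outlier_fraction = 0.05, seed = 101)
flagged <- detect_outliers(sim$data, "repression", seed = 1)
bs <- bootstrap_manifold(flagged, "repression", n_boot = 100, seed = 1)
print(bs)
```

```
<manifold_boot> 100 draws (0 failed), seed=1
  tsat         17.81  [68%: 15.88, 20.46]
  tbg          0.001992  [68%: 0.001741, 0.002216]
  F            21.97  [68%: 20.68, 22.95]
  dg_F         -1.907  [68%: -1.934, -1.87]
```

The TF-DNA binding factor `F` is pinned to a few percent even though
`tsat` is loose (this series has no points near saturation — exactly the
behavior the regime analysis predicts: `F` is read off the parallel
regime 3, `tsat` from regimes 4-5). Here the truth was `F = 23.9`, i.e.
`ΔG_F = -1.96 kcal/mol`; the fitted `-1.91 ± 0.03` shows the ~0.1
kcal/mol scale of both the precision and the residual seed-to-seed
scatter of a 68% interval. Converting factors to energies directly:

```r
round(dg_from_factor(23.9), 2)   # -1.96  (TF-DNA binding)
round(dg_from_factor(712), 2)    # -4.05  (class I TF-RNAP cooperativity)
```

The numbered scripts under `analysis/` run the full study on synthetic
data: `01_simulate.R` writes the datasets (with ground-truth sidecars)
under `results/data/`, `02_fit_repression.R` through `05_titration.R`
fit the repression manifold, the joint shared-`tsat` activation
manifolds, the fixed-`tsat` acceleration model (β ≈ 1 on stabilization
data, β ≈ 3 on accelerated data), and the effector titration
(`F ∝ c^1.41` recovered with a 95% CI). Each writes its tables and JSON
summaries under `results/`.

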