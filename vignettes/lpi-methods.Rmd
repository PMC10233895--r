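---
title: "Methods: growth-based phenotype screening with lpiscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: growth-based phenotype screening with lpiscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `lpiscreen`, the
default parameter values and why they were chosen, what the synthetic
screen generator does and does not emulate, and the numerical decisions
made in the implementation.

# The measurement model

Each colony on an arrayed plate is imaged over time. After optional
calibration to cell counts, colony growth is well described over the
assay window by a logistic curve

$$N(t) = \frac{K}{1 + (K/N_0 - 1)\,e^{-rt}},$$

with inoculum $N_0$, carrying capacity $K$ and maximal specific growth
rate $r$. The quantity of interest is the doubling time $D = \ln 2 / r$,
and all downstream analysis operates on $\log_2 D$: on this scale an
additive shift of $+1$ corresponds to a doubling of $D$, plate-position
effects are approximately additive, and strain noise is approximately
homoscedastic.

## Doubling-time estimation

`estimateDoublingTime()` regresses $\log_2 N(t)$ on $t$ in every sliding
window of `window = 7` consecutive timepoints and takes the window with
the maximal slope among those with $r^2 \ge 0.95$; then $D = 1/\hat\beta$.
Rationale for the defaults:

* **7 points** spans about 2 h at the 20-minute sampling interval —
  long enough to average point noise, short enough to sit inside the
  exponential phase even for fast growers ($D = 1.5$ h gives roughly
  4.5 doublings before saturation effects bend the curve).
* **$r^2 \ge 0.95$** rejects windows straddling lag or saturation, where
  the log-linear model is wrong; on curves with no qualifying window the
  set-level wrapper flags `no_growth` instead of returning a number.
* The estimator is exact on pure exponentials for any window length, and
  scale-invariant: multiplying a curve by a positive constant shifts the
  intercept only, so uncalibrated intensities give the same $D$ as cell
  counts whenever the camera response is linear.

The rolling regressions are evaluated with cumulative sums across all
colonies at once, so a full 9216-curve screen is processed in seconds.

## Smoothing and quality control

`smoothCurves()` applies a running median (`medianWindow = 5`, removes
isolated spikes without biasing level) followed by a running mean
(`meanWindow = 5`, suppresses residual point noise); both windows are
truncated, not padded, at the curve ends. On noise-free data the
smoother is close to the identity, so it changes the $D$ estimate by
well under 1%.

`qcCurves()` rejects colonies that cannot support a growth estimate:
fewer than 10 timepoints, total dynamic range below 2-fold, or a
fraction of strictly decreasing steps above 0.25. Real colonies grow
monotonically up to noise; a curve that decreases at more than a quarter
of its steps is dominated by an artifact (pinning failure, image
segmentation error), not by growth.

# Spatial normalization

Control colonies of a neutral reference strain occupy every fourth
position (both coordinates even), 384 of 1536 positions. For each plate,
`fitControlSurface()` evaluates a Nadaraya–Watson estimate at every
position: a weighted mean of the control $\log_2 D$ values with Gaussian
kernel weights in grid units. `normalizePlate()` subtracts this surface,
which simultaneously removes the smooth spatial bias and the plate's
baseline, leaving $\log_2(D)_{\text{norm}}$ centred on 0 for a neutral
strain.

**Bandwidth.** The kernel-mean estimator has a smoothing bias that grows
with the square of the bandwidth and is worst at plate corners, where
the kernel window is one-sided. The default `bandwidth = 0.8` grid units
was chosen by scanning the bias of the estimator against the generator's
known smooth surface at full 32 × 48 geometry: it keeps the maximum
absolute reconstruction error of a noise-free bias surface below 0.05
log2 units (corners included) while still averaging over several nearby
controls so that control noise is attenuated rather than interpolated.
Larger bandwidths (2–4 grid units) oversmooth the sinusoidal component
of realistic bias fields and leak several times more bias into the
normalized values. A small bandwidth also makes the operation nearly
idempotent: normalizing already-normalized data changes values only
negligibly. The weighted mean is a convex combination of control values,
so the fitted surface can never leave the range of the observed
controls.

# Phenotype calls

For strain $s$ under stressor $c$, each stressor replicate is reduced to
a **log phenotypic index**

$$\mathrm{LPI}_{s,c,i} = \log_2(D)^{\text{norm}}_{s,c,i}
  - \overline{\log_2(D)^{\text{norm}}_{s,\text{background}}},$$

i.e. replicate-level stressor values minus the strain's mean background
value. Defaults of `callConfig()`:

* **Slow-grower exclusion, cutoff 1.5**: strains with mean background
  $\log_2(D)_{\text{norm}} \ge 1.5$ (about 2.8-fold slower than
  controls already without stressor) are excluded before testing. Their
  stressor curves spend most of the assay in lag, making $D$ estimates
  and hence LPIs unreliable, and their hits would conflate general
  sickness with stressor-specific sensitivity.
* **Dual calling criterion**: a strain is called only when a one-sample
  t-test on its replicate LPIs passes Benjamini–Hochberg FDR at
  `alpha = 0.01` *and* $|\overline{\mathrm{LPI}}| \ge 2.5$. The FDR gate
  controls the expected fraction of false discoveries across the ~4300
  simultaneous tests; the effect gate ($2^{2.5} \approx 5.6$-fold,
  reported truncated to one decimal) removes statistically significant
  but biologically small shifts. BH adjustment is performed per
  condition, matching the one-hit-list-per-stressor design.
* **Symmetric resistance**: $\overline{\mathrm{LPI}} \le -2.5$ with the
  same FDR gate yields a `resistant` call.
* **Zero-variance convention**: with identical replicate values and a
  non-zero mean the t statistic is infinite; the p-value is set to 0.
  This arises in noise-free simulations, not in real data.

With the nominal 3 replicates the t-test has 2 degrees of freedom, so
power at the strict α = 0.01 FDR level is sensitive to single lost
replicates; a strain reduced to 2 stressor replicates by QC rarely
reaches significance however large its effect. This is a property of
the design being modeled, not a defect of the implementation.

# Gene-set statistics

`overlapFromCounts()` computes the exact hypergeometric upper tail
$P(X \ge k)$ for the observed intersection of two hit lists drawn from a
finite scored universe (`universeN = 4308`, the number of strains that
pass scoring). Overlap percentages are reported relative to the union of
the two lists. `venn3()` partitions three sets into the seven exclusive
regions. Identifier matching is case-insensitive (identifiers are
upper-cased); no alias resolution is attempted.

# The synthetic screen generator

`simulateScreen()` exists to give the pipeline a ground truth. Per
colony it draws

$$\log_2 D = \log_2(\texttt{baselineD}) + b(\text{row}, \text{col})
  + \text{effect}(s, c) + \varepsilon,\quad
  \varepsilon \sim N(0, \texttt{noiseSd}^2),$$

converts to $r = \ln 2 / D$, and evaluates the logistic curve on the
sampling grid. Defaults and rationale:

* `baselineD = 2.5` h — a typical laboratory-strain doubling time on
  rich solid medium.
* `N0 = 1e5`, `K = 1e7` cells — a ~100-fold dynamic range, i.e. about
  6.6 doublings from pinning to saturation, comparable to colony imaging
  data.
* `samplingInterval = 1/3` h, `duration = 72` h — 20-minute imaging for
  three days, so that even strains slowed 8-fold ($D = 20$ h) complete
  enough doublings to be estimated.
* `biasAmplitude = 0.25` — the spatial bias field (a fixed smooth
  mixture of a linear gradient and a sinusoidal component, identical
  across plates of a screen) has amplitude 0.25 log2 units, i.e. up to
  ±19% in growth rate between plate regions, a realistic magnitude for
  edge and gradient effects.
* `noiseSd = 0.05` — colony-to-colony noise of 0.05 log2 units (~3.5%
  in $D$), consistent with replicate agreement in dense colony arrays.
* `corruptionRate = 0.003` — each curve is independently replaced, with
  probability 0.3%, by pure noise ($N_0 e^{Z}$, $Z \sim N(0, 0.5^2)$,
  per timepoint), emulating failed pinnings; such curves are
  non-monotone and are removed by QC.

**Scope and limitations.** The generator is deliberately minimal: it
adds no per-timepoint measurement noise on top of the parametric curve
(smoothing is therefore exercised by separate seeded-noise unit tests),
no lag-phase variation, no inter-colony competition or nutrient
depletion coupling between neighbours, no replicate-level batch effects,
and the bias field is identical across plates rather than
plate-specific. Planted effects are additive on $\log_2 D$ and constant
across replicates. These simplifications keep ground truth exactly
recoverable, which is what the test suite needs; they also mean
simulation-derived error rates are optimistic relative to real screens.
`simulatePhenotypes()` skips curve generation entirely and draws
normalized $\log_2 D$ values directly — used for fast large-replicate
statistical properties (null false-call rates, power) where the curve
machinery is irrelevant.

The test suite runs most pipeline-level checks on scaled-down 8 × 12
plates with 24-hour assays; this is a test-economy choice of this
package, and the full 32 × 48 geometry is exercised where geometry
matters (layout counts, corruption statistics, the acceptance run).

# Numerical choices

* Logistic evaluation uses the form
  $K / (1 + (K/N_0 - 1) e^{-rt})$, which is monotone and bounded and
  avoids overflow of $e^{rt}$ for large $t$.
* Calibration uses a monotone (Hyman-filtered) cubic spline through the
  supplied intensity/cell-count pairs; monotonicity is required so the
  map is invertible and order-preserving. Negative intensities are
  clamped to zero before mapping.
* Rolling regressions, medians and means are vectorized across the
  colony dimension (cumulative-sum identities; `runmed` per row), so
  runtime is linear in the number of values.
* BH adjustment, t-tests and hypergeometric tails call
  `stats::p.adjust`, `stats::t.test` and `stats::phyper`; the test suite
  verifies each against an independent direct implementation
  (step-up definition, exhaustive subset enumeration).
* All simulation randomness flows from a single integer seed stored in
  the configuration, and identical seeds reproduce a screen
  bit-for-bit.
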