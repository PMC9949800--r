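---
title: "Methods: how calcimech quantifies calcium transients, indentation curves and patch records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how calcimech quantifies calcium transients, indentation curves and patch records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calcimech)
```

calcimech packages three measurement pipelines used to characterise
mechanosensitive-channel (TRPV4) function in chondrocytes: ratiometric
calcium-imaging quantification, AFM nanoindentation analysis, and
patch-clamp summary statistics. This vignette explains the models, the
tunable parameters, the numerical choices, and what the synthetic-data
generators do and do not emulate.

## Ratiometric calcium traces

A `TraceSet` holds per-cell ratiometric fluorescence (calcium-sensitive dye
over a calcium-insensitive reference dye, e.g. Fluo-4 / Fura Red) sampled
at a fixed frame interval `dt` (seconds). Frames before `stimFrame` are the
pre-stimulus baseline; the stimulus (agonist addition) is placed at the
frame boundary immediately before `stimFrame`.

Per cell, four statistics are computed (`analyzeTraces()`):

* **Baseline**: mean $\mu_b$ and sample SD $\sigma_b$ (n−1 denominator) of
  the baseline frames, and the responding threshold $\mu_b + k\sigma_b$
  with $k = 3$ by default.
* **Responder classification**: a post-stimulus frame *responds* when its
  value strictly exceeds the threshold; the cell is a responder when at
  least 25 % of its post-stimulus frames respond. The boundary is
  inclusive (`frac = 0.25` means exactly a quarter qualifies); the strict
  `>` comparison makes the flat-trace case unambiguous (a constant trace
  never responds). The 25 % rule is evaluated over post-stimulus frames
  only, since it quantifies the response to the stimulus.
* **Response latency**: the time of the first post-stimulus frame that
  starts a run of at least two consecutive supra-threshold frames.
  Because the stimulus sits at the boundary before the first post-stimulus
  frame, that frame has elapsed time `dt`, not 0 — latencies are positive
  times measured from the addition of stimulus. A classified responder
  with no two-consecutive-frame run yields an absent onset (`NA`) and is
  excluded from onset summaries.
* **Peak-filtered AUC**: computed on the baseline-subtracted trace
  $y(t) = \mathrm{value}(t) - \mu_b$ over the post-stimulus window, so the
  conventional "baseline of Y = 0" is meaningful. Peaks are maximal runs
  with $y > 0$; a peak whose maximum height is below 10 % of the
  min-to-max range of $y$ over the window is ignored; the area of each
  kept peak is the trapezoidal integral of the positive part of the
  piecewise-linear trace, with zero crossings interpolated linearly
  (crossing panels contribute exact triangle areas, so the total is
  additive over peaks and scales linearly with the trace). Whether
  published trace plots were baseline-subtracted before integration is not
  something the analysis description pins down; subtraction is this
  package's default, and `window = "full"` / a raw-trace baseline are
  available through the function arguments.

Group summaries (`summarizeTraces()`) report responder counts, mean ± SEM
of the AUC over all cells, and mean ± SEM of the onset over responders
only.

### Synthetic traces

`genTraces()` draws i.i.d. Gaussian baseline noise
$\mathcal{N}(\mu_b, \sigma_b)$ for every cell and adds, for a programmed
fraction of responder cells, a transient
$A\,(1 - e^{-(t-t_0)/\tau_r})\,e^{-(t-t_0)/\tau_d}$ normalised to unit
peak, so `amplitude` is the actual peak height in ratio units and
signal-to-noise conditions like "amplitude = 10 σ" mean what they say. The
latency $t_0$ is drawn from a normal distribution truncated at zero
(resampling), reflecting that a response cannot precede the stimulus.

Defaults emulate the imaging protocol the pipeline was built for: 100
baseline frames and 300 post-stimulus frames. The acquisition rate is not
published exactly (100 frames ≈ 6 min and 300 frames ≈ 20 min imply
slightly different rates), so `dt` is a single configurable value with
default 4.0 s. The transient defaults (rise 2 s, decay 600 s) emulate the
fast onset and sustained plateau of agonist-evoked calcium influx through
a non-inactivating channel, which remains elevated across a ~20 min
recording; with a much faster decay the generated "responders" would not
satisfy the 25 %-of-frames rule, i.e. the ground-truth labels would not
describe the generated data. Latency defaults (mean 40 s, SD 10 s) sit in
the range of published response times for agonist-stimulated cells
(~10–50 s).

Noise is i.i.d. Gaussian everywhere; photon-limited (Poisson) noise,
photobleaching, and cell motility are deliberately not modelled — the
analysis assumes none of them, so tests on synthetic data validate the
estimators, not the robustness of the pipeline to optical artefacts in
real recordings.

## Imaging pipeline

`segmentCells()` reimplements the classic ImageJ recipe: maximum-intensity
projection of the reference (red) channel over time — so cells are found
even if they never signal — followed by a global threshold, a
distance-transform watershed to split touching cells, and a particle-size
gate discarding regions below `minArea` pixels (default 100, the
"100-infinity" size filter; no pixel calibration is assumed). The original
description does not record which threshold, median radius or watershed
variant was used, so each is configurable with documented defaults: Otsu
threshold (invariant to affine intensity rescaling), median radius 1 px
(3 × 3), EBImage's distance-map watershed with tolerance 1. Labels are
renumbered by decreasing area with centroid tie-breaks so output is
deterministic.

`ratioStack()` median-filters both channels per frame and divides green by
red. Pixels whose filtered red intensity is at or below 1 % of the red
maximum are masked invalid (NA) rather than clamped: at cell boundaries
the 3 × 3 median of a mostly-background neighbourhood collapses the
reference signal to the noise floor, and dividing by it would inject
arbitrarily large ratio values into the cell means. The 1 % default sits
above the noise floor of a typical detector while staying far below any
real in-cell dye level. `extractTraces()` then averages the valid ratio
pixels per label and frame; a cell with no valid pixel in some frame is
dropped with a warning, never silently.

## AFM nanoindentation

A `ForceCurve` stores piezo extension $z$ (µm), cantilever deflection $d$
(nm) and probe metadata (spring constant $k$ in N/m, default 7.83; tip
radius $R$ in µm, default 2.5, i.e. a 5 µm sphere; Poisson's ratio $\nu$).
Force is $F = k d$ (nN). The elastic modulus comes from the
spherical-indenter Hertz model with a cantilever-deflection correction
(the "modified" Hertz analysis):

$$F = \frac{4}{3}\,\frac{E}{1-\nu^2}\,\sqrt{R}\,\delta^{3/2}, \qquad
  \delta = (z - z_0) - d,$$

with the unit contract F in nN and lengths in µm giving E directly in kPa.

* **Contact point** (`findContactPoint()`): since $F^{2/3}$ is linear in
  the tip–sample separation, $F^{2/3}$ is regressed on the
  deflection-corrected abscissa $z - d$ over the 10–90 % force window and
  extrapolated to zero force; the window is re-selected once relative to
  the first estimate and the regression repeated. In the rigid-cantilever
  limit this reduces to regressing on $z$ itself. Curves that never rise
  at least 10× above the pre-contact RMS noise are reported as fit
  failures (the probe never contacted the sample).
* **Modulus** (`fitHertz()`): with $z_0$ fixed, $F = C \delta^{3/2}$ is
  linear in $C$, so the least-squares minimiser is closed-form,
  $C = \sum F\delta^{3/2} / \sum \delta^{3}$ — no iterative optimiser and
  no convergence tolerance are needed. The default 10–90 % force window
  avoids baseline noise at one end and deep-indentation nonlinearity at
  the other. $\nu$ is rarely reported for tissue; the default 0.5
  (incompressible) is configurable, and changing it rescales E by exactly
  $(1-\nu^2)$.
* **Maps** (`makeGrid()`, `analyzeMap()`): indentation sites form a square
  lattice with `floor(side/spacing)` points per axis at half-spacing
  offsets — a 10 µm × 10 µm region at 0.5 µm intervals gives exactly
  20 × 20 = 400 indentations, which pins the convention. Per-map
  summaries (mean, median E) are computed over successful fits only, with
  the failure count always reported.

`genForceCurve()` builds curves from the same model: zero force plus noise
before contact, then the Hertz relation solved self-consistently for the
deflection coupling by fixed-point iteration (tolerance 1e-6 nN, at most
100 iterations; the iteration map is a contraction for any physical
parameter combination, e.g. at 15 kPa and k = 7.83 N/m its derivative is
below 0.01). Curves are truncated at a maximum force of 300 nN by
default, matching the instrument protocol the pipeline targets.

## Patch-clamp statistics

* `currentDensity()` divides whole-cell current (pA) by membrane
  capacitance (pF).
* `deltaCurrent()` isolates the channel-specific current as each basal
  cell's density minus the *mean* density of the antagonist-inhibited
  group: $\Delta_i = \mathrm{basal}_i - \overline{\mathrm{inhibited}}$.
  By construction $\overline{\Delta} =
  \overline{\mathrm{basal}} - \overline{\mathrm{inhibited}}$ exactly, and
  the SEM is taken over the basal cells with the reference mean treated as
  a constant — matching the per-cell-minus-group-average construction of
  the statistic. Groups at different holding potentials are refused.
* `unitaryCurrent()` estimates the single-channel current step from the
  all-points amplitude histogram by fitting a two-component Gaussian
  mixture with EM (k-means initialisation, 10 restarts, best likelihood
  kept, SD floor 1e-6 of the data range to avoid singular components) and
  reporting $|\mu_{open} - \mu_{closed}|$ as a magnitude (inward currents
  are negative by convention). Records whose minor component carries less
  than 1 % of the weight, or whose two means collapse, are reported as
  "no second level detected"; a record with exactly two support points
  (noiseless) is resolved exactly without EM. The estimate is invariant
  to constant offsets.

`genPatchTrace()` simulates a two-state telegraph process with
exponentially distributed dwell times at 3 kHz sampling; the stationary
open probability and the mean open dwell determine the closed dwell. It
does not model capacitive transients, leak, filtering, or sub-conductance
states — it validates the amplitude estimator, not event detection.

## Cross-cutting statistics

* `routOutliers()` implements the robust-outlier procedure for column
  data: because the published method is defined for regression, the
  constant-only model is adopted (centre = median). The robust scale
  (RSDR) is the 68.27th percentile of absolute residuals with the
  small-sample correction $n/(n-K)$, $K=1$; residual t statistics
  (df = n−K) are tested from the most extreme inward, flagging while
  $p_{(i)} \le Q\,i/n$ and stopping at the first non-rejection (a
  Benjamini–Hochberg-style step at FDR Q, default 1 %). The exact
  small-sample constants of the proprietary implementation are
  unpublished; the published construction is used as stated. Flagged
  points are always reported alongside kept ones. In simulation the
  fraction of clean normal datasets (n = 20) with any flag is ≈1–1.5 %,
  consistent with the design rate.
* `meanSEM()` reports mean, SD/√n (n−1 SD) and n; `ddct()` implements the
  relative-quantification transform $2^{-\Delta\Delta C_T}$ against a
  housekeeping gene and reference condition.
* Named omnibus tests (Kruskal–Wallis, ANOVA, post hoc comparisons) are
  not re-implemented; they are one `stats::` call away on the tables this
  package produces.

## Interchange formats and conventions

Traces travel as CSV (one column per cell, header of cell ids) with a JSON
sidecar holding `dt`, `stim_frame` and units; force curves as CSV with the
unit-suffixed header `z_um, deflection_nm` (checked bit-exactly) plus a
probe JSON (`k_N_per_m`, `R_um`, `nu`); stacks as one 16-bit multi-page
TIFF per channel with intensity scale factors in a sidecar. On disk,
`stim_frame` is a 0-based index (a language-neutral contract); inside R
the `TraceSet` slot `stimFrame` is the 1-based index of the first
post-stimulus frame, and the readers/writers convert. Times are seconds,
moduli kPa, currents pA, capacitances pF. Schemas are versioned; readers
reject a newer major version.

Every generator takes one explicit integer seed and is bit-reproducible;
`runPipeline()` threads a single seed through all stages and writes a
resolved-config copy and a run report next to its outputs, so any output
is reproducible from (config, seed) alone.

## Problem sizes used in the test-suite and acceptance runs

Validation runs use cohorts of 200 synthetic cells at the full 100 + 300
frame protocol for trace statistics; a 100-cell, 220 × 220 px, 80-frame
stack for the end-to-end imaging round trip (20 baseline + 60
post-stimulus frames — enough for stable baseline statistics and the
25 %-rule while keeping the stack comfortably in memory); 50 noisy curves
per modulus in 10–20 kPa (the physiological range of interest) for Hertz
recovery; 3 s of 3 kHz single-channel record for the unitary-current
check; and 10^4 replicates of n = 20 for the outlier false-flag rate.
These sizes give the recovery statistics quoted above reproducibly across
seeds.

## Known limitations

The imaging module assumes stationary cells and 2-D segmentation of a
maximum projection; the indentation module fits a purely elastic
half-space (no viscoelasticity, no thin-sample correction) on the
approach curve only; the patch module estimates amplitudes, not kinetics.
Passing the synthetic-recovery tests demonstrates the estimators are
correct under the stated noise model, not that real recordings satisfy
that model.
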