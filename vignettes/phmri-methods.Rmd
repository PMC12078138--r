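---
title: "Dose-response phMRI: volume of activation and resting-state networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-response phMRI: volume of activation and resting-state networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem this package addresses

Pharmacological MRI (phMRI) follows the brain's haemodynamic response to a
drug delivered *during* the scan. In the awake-rodent paradigm this package
models, each session is 250 BOLD acquisitions at TR 6 s (25 minutes): the
first 50 scans (5 minutes) precede the injection and serve as the control
window, and a late post-injection interval — scans 200–240 — is the
stimulation window in which the drug effect is tested. Sessions are
registered to a segmented atlas (at full scale, 169 areas grouped into 11
macro-regions), and the questions are (a) *where* and *how much* of each
region's tissue responds, per dose, and (b) how region-to-region
resting-state coupling reorganises with dose.

The package implements both analysis arms end-to-end, plus a synthetic-data
generator with known ground truth, so that every stage can be validated by
parameter recovery rather than by eyeballing maps.

## The evoked arm: volume of activation (VoA)

Per voxel $v$ and acquisition $t$, percent change is taken against the
control-window mean $B(v)$:

$$\mathrm{pc}(v,t) = 100\,\frac{S(v,t) - B(v)}{B(v)}.$$

Three decisions define the statistic:

1. **The 1% floor.** A voxel enters testing only if $|\mathrm{pc}|$ reaches
   1% at least once anywhere in the post-injection period (not merely in the
   stimulation window). Spontaneous fluctuations in the awake brain sit
   around ±1%, so the floor is a conservative screen against noise; it is a
   preprocessing step, not a significance claim. The boundary is inclusive
   (a peak of exactly 1.0% is kept).
2. **One-sample t against zero change.** Over the stimulation window's
   $n = 40$ values, $t = \bar{\mathrm{pc}}/(s/\sqrt{n})$, $df = n-1$,
   two-tailed. A Welch baseline-vs-stimulation two-sample variant is
   available (`voxel_ttest_welch()`) for sensitivity analyses.
3. **The FDR filter.** With the included voxels' p-values sorted ascending,
   the largest rank $i$ with $P_i \le (i/V)\,q/c(V)$ defines the pass set
   (step-up; ties share the qualifying rank). $c(V)=1$ is the classical
   Benjamini–Hochberg choice for independent/positively dependent tests;
   the universe $V$ is the floor-included voxels of that subject's mask,
   because filtering precedes testing. The default target is $q=0.05$;
   both $q$ and $c(V)$ are config fields because reported practice varies,
   and the "FDR was p = x" style summary is computed as the BH-adjusted
   p-value at the cutoff rank.

Positive and negative VoA are then the per-region counts of significant
voxels by the sign of the stimulation-window mean change, also normalised by
region volume. Group composite maps pull each subject's window-mean map into
atlas space through the *inverse* of its affine transform with trilinear
interpolation, averaging only in-bounds contributions — out-of-bounds
samples are flagged and excluded rather than silently averaged as zeros.

Dose effects per region are ranked by a Kruskal–Wallis test (tie-corrected
H, chi-square p on $k-1$ df) with the same step-up FDR applied across
regions. The effect size reported with each row is
$\omega^2 = (H - k + 1)/(n - k)$; the epsilon-squared variant
$H\,(n+1)/(n^2-1)$ is available behind a flag. Published VoA tables rarely
state which variant produced their printed effect sizes, so the package
exposes both and asserts neither.

## The resting-state arm

Region mean series (200 timepoints at TR 1 s in the default generator) are
band-pass filtered to 0.01–0.1 Hz, detrended, and optionally cleaned by
nuisance regression (six motion parameters, spike indicators from a
framewise-displacement screen, tissue means). All $N(N-1)/2$ region pairs
(14,196 at 169 regions) get a Pearson $r$, Fisher-transformed to
$z = \mathrm{atanh}(r)$. Across the subjects of a group, each edge's $z$
values feed a one-sample t-test whose two-sided p is mapped back to a
standard-normal scale preserving sign ($Z = \mathrm{sign}(t)\,
\Phi^{-1}(1 - p/2)$); the raw-t alternative is a config choice. Thresholding
at $|Z| \ge 2.3$ yields the binary graph; $|Z|$ on suprathreshold edges
provides the weights for weighted degree.

Graph metrics follow the standard definitions: density
$2|E|/(n(n-1))$, average degree $2|E|/n$, average path length as the mean
unweighted shortest-path distance. On disconnected graphs the default
averages over connected pairs and reports the disconnected-pair count; a
largest-component variant is provided, since graph tools differ silently on
this convention. Profile clustering uses mutual k-nearest neighbours on the
Z-matrix rows (correlation distance computed excluding the two self-entries
of each pair, ties at the k-th neighbour included so the result is
order-independent); connected components of the mutual graph are the
resting-state networks.

## What the generator emulates — and what it does not

`sim_config()` pins the synthetic study to the acquisition above. Choices
that were genuinely open, and how they were fixed:

* **Response shape.** A linear ramp from the first post-injection scan to a
  plateau at the stimulation-window start, sustained thereafter. The evoked
  responses this emulates show an immediate rise and sustained elevation;
  the ramp-to-plateau is the simplest shape with those features, and its
  plateau (3% at the high dose) sits in the 2–4% range typical of strong
  somatosensory responses.
* **Dose staircase.** Plateau amplitudes 0/1/2/3% and responsive extents
  0/0.3/0.5/0.8 for vehicle/0.03/0.3/3.0 mg/kg — a monotone staircase in
  both amplitude and spatial extent, the pattern regional VoA summaries
  show. These are the fixed study conditions for all recovery tests.
* **Noise.** AR(1) temporal noise (coefficient 0.3) with stationary SD 0.5%
  so that spontaneous excursions sit near the ±1% floor, plus optional
  linear drift and global spike frames. No published per-voxel variance or
  spatial autocorrelation was available to calibrate against; the SD was
  chosen to make the 1% floor meaningful (it includes roughly the upper
  half of null voxels over a 200-scan post-injection period). Note that
  positive autocorrelation makes the voxelwise t anticonservative — the
  null-calibration checks therefore use independent noise
  (`ar1_coefficient = 0`), which is also the regime in which the
  floor+BH chain is shown to hold its nominal rate.
* **Resting-state structure.** Non-hub regions split into 4 communities
  sharing latent signals (within-community $r = 0.6$). The hub region
  stands outside the communities and shares one private factor with each
  of 4 partners ($r = 0.4$ per edge), so partners do not inter-correlate
  through the hub. The hub edge strength was set from the measured
  between-subject SD of post-filter Fisher z (≈ 0.17 at 200 timepoints):
  at 6 subjects per group each planted edge clears $|Z| = 2.3$ with ≈ 99%
  power, which is what makes the ≥ 95%-of-seeds hub-recovery contract a
  property of the design rather than luck.
* **Determinism.** Planted *structure* (partner sets) derives from the
  config seed — it is a property of the condition, shared by all subjects —
  while per-session noise derives from the session seed. Same seeds, same
  bytes.

The generator does **not** emulate: haemodynamic response convolution,
k-space/scanner physics, susceptibility or motion artifacts beyond global
spikes, spatial noise correlation, or deformable anatomy (transforms are
affine inputs). Passing recovery tests therefore demonstrates the
*statistical chain* is correct under the declared noise model, not that the
pipeline is robust to every artifact of real acquisitions.

## Numerical choices and degenerate inputs

* Coordinates are 0-based with voxel centres at integers; scan intervals
  are half-open `[start, stop)`. Trilinear sampling clamps the 8-corner
  stencil at the upper faces (where the fractional weight toward the
  clamped corner is zero) and returns a flagged fill value (default 0)
  outside the volume.
* Label volumes are categorical: they are written with an integer datatype
  and would be resampled nearest-neighbour, never interpolated.
* `bandpass()` centres the series before the zero-phase (forward–backward)
  order-2 Butterworth filter: the stop-band removes DC in steady state
  anyway, and centring avoids the large edge transients `filtfilt`
  produces on offset series.
* Zero-variance voxels in the t map take $p = 0$ (nonzero mean) or $p = 1$
  (all-zero) and are QC-flagged; zero-variance edges in the group Z matrix
  are capped at a documented value (default 8) and flagged; zero-variance
  regions are excluded from graphs rather than propagating `NA`.
* The Kruskal–Wallis $\omega^2$ can be slightly negative under the null; it
  is reported as computed with a floored display column.
* Motion scrubbing converts outlier scans (framewise displacement above
  0.2 mm, rotations taken as arc length at 5 mm radius) into spike
  indicator regressors instead of deleting frames, preserving the time
  grid.

## Problem sizes used by the tests and the acceptance script

The validation suite runs the full pipeline at a 32×32×8 grid with 12
regions (≈ 7,200 brain voxels) and the full 250-scan timing — small enough
to iterate quickly, large enough that voxel counts, FDR behaviour and graph
structure are non-trivial. Null calibration uses 20 seeds of the
zero-amplitude generator and 2,000 null Kruskal–Wallis tables at 12
subjects per dose group (the study-scale design); recovery uses 20 seeds
each for sensitivity, extent, and hub rank, and 16 subjects for the dose
staircase. Oracle-equivalence checks (step-up FDR vs brute force, graph
metrics vs BFS, Pearson/trilinear/OLS vs direct formulas) are exact.

## Known limitations

* The per-subject FDR universe couples doses: as true activation grows, the
  BH cutoff loosens and admits more sign-negative false positives, so
  negative VoA can itself show a dose trend in positive-only simulations.
  This is a property of the published procedure, reproduced faithfully.
* With AR(1) noise the one-sample t over the stimulation window is
  anticonservative (the baseline-mean estimate also correlates all of a
  voxel's percent-change values). The pipeline reports what the procedure
  computes; calibration guarantees are stated for independent noise only.
* Group sizes below ~5 leave little power for per-edge one-group t tests at
  $|Z| \ge 2.3$; hub recovery is specified at 6 subjects per group.
* The chi-square Kruskal–Wallis approximation is conservative for very
  small groups (exact size ≈ 0.022 at 3 per group); nominal-size behaviour
  holds at the study-scale 12 per group.
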