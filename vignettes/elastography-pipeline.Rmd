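---
title: "From force-distance curves to stiffness-gradient kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From force-distance curves to stiffness-gradient kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elastomap)
```

elastomap analyses time-lapse in vivo AFM (atomic force microscopy)
elastography of developing brain tissue: repeated grids of indentation
measurements taken over the region where the optic tract (OT) makes its
stereotypical caudal turn. The pipeline turns raw approach curves into
spatiotemporal stiffness maps, quantifies the rostro-caudal stiffness
gradient ahead of the advancing tract, extrapolates when that gradient
appeared relative to when the axons started turning, and computes the
companion image metrics (nuclear densities, tract elongation, Sholl
profiles, mitotic-cell densities). This vignette explains the models, the
parameters that matter, and the design choices behind each stage.

## The contact model and curve-level quality control

Each grid point yields one approach segment: piezo height $z$ (µm) against
cantilever deflection $d$ (µm) or force $F = k d$ (nN), with spring
constant $k$ (N/m) supplied by the instrument's thermal calibration.
`fit_hertz()` models the contact region with the Hertz relation for a
spherical probe of radius $R$,

$$F = \tfrac{4}{3}\, K\, \delta^{3/2} \sqrt{R},$$

where $K = E/(1-\nu^2)$ is the reduced apparent elastic modulus reported
per point — the Poisson ratio never enters separately — and
$\delta = (z - z_c) - F/k$ is the tip–sample separation beyond the contact
point $z_c$. The contact point is not observable directly, so it is scanned
over candidate samples; at each candidate, $K$ has a closed-form
least-squares solution because the model is linear in $\delta^{3/2}$, and
the winning $(z_c, K)$ pair (lowest total squared residual, counting
pre-contact samples against a zero-force model) is refined by bounded
continuous optimisation. This admits a brute-force oracle — a fine grid
over $z_c$ with the same closed form — which the test suite compares
against directly.

Two exclusion rules mirror standard curve QC: (1) *baseline* — the
non-contact region cannot be fitted by a line (residual sd above 25% of the
10 nN analysis force, or no detectable contact); (2) *hertz_fit* — the
Hertz fit does not align with the data (RMS residual above 10% of the
analysis force, fit $R^2 < 0.8$, or the curve never reached the analysis
force). The baseline window is the first 60% of samples before a
provisional contact (first sustained exceedance of the baseline noise by
5 sd). All thresholds are arguments with these defaults. "Analysed at the
maximum applied force of 10 nN" is implemented as a fit-range cap: the fit
uses the full contact region up to 10 nN.

## Smoothing and imputing the stiffness array

Per-frame maps are stacked into an $x \times y \times t$ array and smoothed
by penalized least squares in the discrete cosine basis: minimise
$\lVert W^{1/2}(y - z)\rVert^2 + s \lVert \Delta z \rVert^2$ with the
second-difference (Laplacian) penalty under reflective boundaries. The
type-II DCT diagonalises the operator (per-axis eigenvalues
$2 - 2\cos((i-1)\pi/n)$), so smoothing is a spectral filter
$1/(1 + s\Lambda^2)$; missing nodes (weight zero) are imputed by iterating
the filter to its fixed point, which borrows strength from the entire
array rather than only neighbours. One scalar $s$ applies to all axes,
with each axis's eigenvalues scaled by its physical step (20 µm spacing,
~35 min frame interval), keeping the penalty geometry-aware. $s$ is chosen
by generalized cross-validation over a log-spaced search in
$[10^{-6}, 10^6]$, refined by bounded scalar minimisation; the optimiser is
verified against a 200-point brute-force scan.

The robust mode re-weights residuals with the bisquare function (tuning
constant 4.685, approximately 95% Gaussian efficiency) on studentised
residuals, using the exact average leverage $\mathrm{tr}(H)/n$ from the
eigenvalue filter. Following the original analysis, standard smoothing
feeds the quantitative gradient series while robust smoothing is intended
for display arrays such as fold-change montages; both are exposed on every
entry point.

Numerical choices: the missing-data fixed point iterates to a relative
tolerance of $10^{-12}$ (capped at 20,000 cheap DCT passes), which keeps
the solution within $10^{-8}$ of a dense solve of
$(W + s\Delta^{\top}\Delta) z = W y$ on test-sized arrays. With full
weights the filter is applied in a single exact pass. Degenerate inputs
(all-missing arrays, constant series where rescaling is undefined) raise
errors rather than guessing.

## The gradient statistic and its ROIs

Stiffness gradients use mean $K$ over two 50 × 50 µm² regions of interest
flanking the tract, $(K_R - K_C)/50\,\mu m$, positive when the rostral
side is stiffer. Boxes are half-open (a node on the shared edge of two
abutting boxes counts once). Each frame is measured with three replicate
placements and the per-replicate gradients averaged. For synthetic scenes
the placements flank the map mid-line at a 10 µm standoff, shifted ±20 µm
along y for replicates; real analyses supply manual placements as JSON.
There is no canonical standoff — it is a configuration value. Fold-change
maps divide each frame by the previous frame (first frame set to 1) or by
the first frame, always on the smoothed, imputed series, since ratios of
raw maps with missing nodes are ill-defined.

## Onset extrapolation and the gradient-to-turning delay

Gradient and turn-angle series are rescaled per animal to $[0, 1]$
(min to 0, max to 1) and fitted with a first-degree polynomial; the onset
is the time where the fitted line crosses 0 — the natural level, since the
per-series minimum maps to 0; the crossing level is configurable. The
delay is the difference of the two onsets, computed per scene before any
cohort averaging.

One design point deserves emphasis. A straight line fitted through *all*
frames of a series that is flat and then ramps up crosses zero well before
the true onset, and by different amounts for two series with different
onsets — in simulation this shrinks recovered delays to roughly half their
injected value. The default fit therefore starts at the first frame
exceeding 10% of the rescaled range (`fit_window = "rise"`); for series
that rise throughout the recording — the regime in which these global
linear fits reach $R^2 \approx 0.99$ — the rise window and the all-frames
fit coincide, and `fit_window = "all"` remains available.

## What the synthetic scenes emulate

`afm_scene()` bundles the ground truth and noise model from which every
input is generated. Probe and ramp defaults are the experimental settings:
$R = 18.64$ µm spherical probe, $k = 0.03$ N/m (selected range
0.02–0.04), 10 nN maximum force, 5 µm/s approach at 1000 Hz, grids of
13 × 8 nodes at 20 µm sampled every 35 min for 8 frames (~150 × 250 µm
over ~4 h). The stiffness field is uniform at 150 Pa until the gradient
onset (40 min into the recording), then a rostro-caudal gradient grows at
0.02 Pa/µm per min — reaching ~0.9 Pa/µm, the magnitude associated with
the first detected axon turning, about 45 min after onset — realised as
80% rostral stiffening and 20% caudal softening, the "mostly rostral"
split. The plateau (4.5 Pa/µm) lies beyond the recording window so the
series still rises at its end, matching the near-perfectly linear rescaled
series of the source experiments. The time ramp is a piecewise-linear
hinge because the generator's contract is exact: zero gradient before
onset, linear growth at the stated rate after it; a logistic ramp of the
same limiting slope is available via `ramp_shape = "logistic"` for
sensitivity checks. Absolute moduli are conventions (embryonic brain
tissue at tens to hundreds of Pa), not reproductions of any published
colour scale.

Curve noise is additive Gaussian force noise (0.05 nN, i.e. ~50 pN),
a drifting linear baseline, and node dropout: with probability 0.1 a node
yields a pure-noise stub with no contact region, which trips the baseline
exclusion naturally. The tract is three landmarks (chiasm, bend, end)
whose turn angle is zero until gradient onset plus an 18 min delay, then
grows at 0.3 deg/min; each frame is "measured" as the mean of three noisy
repeats (0.5° each), and gradient samples likewise average three noisy
replicates (0.035 Pa/µm each). These replicate noises put the rescaled
series in the $R^2 \gtrsim 0.99$ regime reported for the real fits, so
the delay-recovery experiment (50 scenes, injected delays 5–30 min)
measures estimator bias rather than sampling scatter; the recovery
regression slope stays within [0.9, 1.1] under these conditions. Nuclei
images are a hard-disk point process per image half (4 µm nuclei at
0.5 µm/px, realistic confocal sampling) that reports its realised painted
fractions, giving the density chain a pixel-count ground truth.

What the generator does *not* emulate: cantilever dynamics, adhesion,
viscoelastic creep, spatially textured stiffness within each half,
curved tracts, nucleus intensity variation or clumping beyond hard-disk
exclusion. Passing tests therefore demonstrate that the analysis recovers
the parameters of data with this statistical structure — not that it is
robust to every artefact of live-embryo measurements.

## Image metrics

* **Turn angle** — interior angle at the bend between the chiasm→bend and
  bend→end segments, subtracted from 180°, signed positive when the end
  deviates toward caudal (+x); repeats are averaged.
* **Tract elongation** — major-to-minor axis ratio of the ellipse with the
  same normalized second central moment as the binary tract mask
  (eigenvalues of the pixel-coordinate covariance).
* **Nuclear density** — Gaussian blur (σ = 2 px), threshold, binarise,
  filter components by size ≥ 1 px² and circularity $4\pi A/P^2 \in
  [0.2, 1]$, then retained area over ROI area. The manually adjusted
  threshold of the original protocol becomes an explicit parameter with
  Otsu as the no-information default; for synthetic images the principled
  choice is 0.5 of the normalized range, since a Gaussian-blurred binary
  edge crosses half-maximum at the true boundary. Components touching the
  ROI border are exempt from the circularity floor (their perimeter is
  truncated by the crop), which also makes a fully saturated ROI score 1.
  Computed circularities above 1 (a discretisation artefact of small
  components) are clipped to 1.
* **Sholl profile** — concentric circles from a start radius derived from
  the fitted explant-ellipse area $A$, stepping 5 µm, counting contiguous
  foreground runs along each sampled circle. The printed start-radius rule
  "$R = A/\pi$" is dimensionally inconsistent (µm² per µm), so the default
  is $\sqrt{A/\pi}$ with the literal rule selectable. The "median
  outgrowth radius" is not operationally defined by a Sholl profile, so
  the package documents a reach-based proxy: the largest radius up to
  which the crossing count has not fallen below half the count at the
  start radius.
* **pH3 density** and **normalized brain area** — forced arithmetic:
  counts per 10,000 µm², and exposed-to-intact area ratio.

Coordinates follow one convention throughout: x increases rostral→caudal,
y dorsal→ventral, image matrices are indexed (row = y, col = x), boxes are
half-open.

## The end-to-end runner

`run_pipeline()` chains simulation → curve fitting → smoothing → gradient
series → turn angles → onset kinetics → fold-change maps → (optionally)
the nuclei-density stage with its density–stiffness Pearson correlation,
writing per-stage artefacts (curve QC table, raw/smoothed/fold-change
series with JSON sidecars, gradient and kinetics CSVs, ROI/trace JSON) and
a manifest with versions, parameters and per-stage counts. All numeric
output uses fixed formatting, so a rerun with the same seed is
byte-identical. Configs are YAML or JSON validated against the schema of
`default_run_config()`; unknown keys are errors. The density stage uses
three stage windows (0–90, 90–180, 180–280 min) with painted fractions
rising rostrally (0.20/0.28/0.35) against a nearly flat caudal side
(0.20/0.21/0.23), emulating the later-stage density difference; its
correlation against the binned stiffness gradient is computed on three
stage pairs, so the Pearson coefficient is a three-point summary, not an
inferential statistic.

Problem sizes used throughout the tests and the acceptance script — 200
simulated curves for fit recovery, arrays up to 8 × 8 × 4 against the
dense oracle, 50 scenes for delay recovery, the 13 × 8 × 8 default scene
for end-to-end runs — were chosen so each check isolates one property at
comfortable statistical resolution.

## Known limitations

* The contact-point scan assumes a single contact event per curve;
  curves with multiple touch-downs (debris, overhangs) will fit the first
  consistent region or be excluded, not segmented.
* GCV can undersmooth very small arrays with strong structure; the search
  bounds $[10^{-6}, 10^6]$ assume grids up to ~100 nodes per axis.
* The turn-angle sign convention needs a caudal direction vector; for
  traces whose deviation is exactly orthogonal to caudal the sign is
  taken as positive.
* The density chain's accuracy degrades for nuclei smaller than about
  twice the blur sigma; at the defaults (8 px nuclei, σ = 2) the
  round-trip error stays under 0.02 area fraction up to 0.4.
* Onset extrapolation assumes an approximately linear rise; strongly
  saturating series should be windowed to the rising phase explicitly.
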