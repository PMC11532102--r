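---
title: "Quantifying muscle-fiber morphology from edge-probability maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying muscle-fiber morphology from edge-probability maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibertrace)
```

## The measurement problem

Healthy skeletal muscle regenerates as long, straight, parallel myofibers.
Poorly regenerating muscle — chronic pressure ulcers are the canonical case —
instead shows wavy, split and non-parallel fibers. In fluorescence
micrographs the most reliable signature of these malformations is the
geometry of the *fiber edges*: a bundle of straight parallel fibers produces
long straight edge segments with tightly clustered orientations, while
malformed tissue produces shorter, curvier segments pointing every which way.

`fibertrace` turns a per-pixel edge-probability map $P(E)$ of a calibrated
micrograph into a set of measured edge segments and summarizes each image by
four biomarkers:

* **median tortuosity** $\tau = c/d$, the arc-chord ratio of a segment's
  traced path length $c$ over its end-to-end chord $d$ (straight segments
  give exactly 1);
* **segment density**, the count of surviving segments per mm$^2$;
* **median edge segment distance**, the median of the traced path lengths
  $c$ in µm;
* **orientation dispersion**, the population SD and the interquartile range
  of the chord angles $\theta = \operatorname{atan2}(h, w)$ folded into
  $[0, \pi)$, where $(h, w)$ are the vertical/horizontal chord components.

Groups of images (one row per image) are then compared by one-way ANOVA with
Tukey–Kramer post hoc tests.

## Pipeline stages and their parameters

The stage order is fixed: preprocess → probability → non-maximum suppression
→ double threshold → hysteresis → skeletonize → clear border → graph →
filter → biomarkers. Everything is deterministic; only the synthetic
generator consumes randomness.

**Probability backends.** The probability map can be (a) loaded from a
grayscale file (`probfile`; `invert = TRUE` for maps exported with a white
background), (b) computed as a Gaussian-smoothed gradient magnitude
(`gradient`, `smooth_sigma_px = 2`), a weight-free classical detector, or
(c) taken directly from rescaled image intensity (`intensity`). The third
backend exists because ridge-like inputs — synthetic fiber scenes, or
detector outputs saved as images — *are* already edge-probability surfaces;
routing them through the identical thinning/tracking path is what lets the
generator's ground truth be recovered one-segment-per-fiber and makes the
whole pipeline testable end to end.

**Non-maximum suppression.** The local edge tangent is estimated from the
gradient of the smoothed map (the angle perpendicular to the gradient,
folded to $[0,\pi)$; flat regions get 0 by convention). A pixel survives iff
its value times a multiplicative tolerance (default 1.01) is at least the
bilinearly interpolated map value one pixel away on *both* sides along the
normal. The tolerance breaks plateau ties in favour of retention — without
it, two equal neighbouring crest pixels would annihilate each other and
leave gaps; the resulting occasional two-pixel-wide crossings are resolved
by skeletonization. Border pixels compare only against in-bounds samples.

**Double threshold and hysteresis.** Pixels above `th` (default 0.3) are
strong, below `tl` (default 0.1) weak, and boundary values are intermediate
(`tl <= I <= th`). The defaults are package choices on the $[0,1]$
probability scale and should be reviewed per detector. Two tracking rules
are provided: the classical *transitive* rule (default) keeps an
intermediate pixel iff it is 8-connected to a strong pixel through a chain
of intermediate/strong pixels; *one_hop* keeps it only with a strong pixel
directly in its 8-neighbourhood. The one-hop reading matches the literal
"any of their surrounding neighbors" description of hysteresis, the
transitive rule is what edge-tracking implementations actually do; both are
kept so either convention can be reproduced, and transitive output always
contains the one-hop output.

**Skeletonization.** Zhang–Suen parallel thinning iterated to convergence,
followed by sequential removal of *simple points* (pixels whose deletion
provably preserves 8-connected foreground topology: one foreground component
in the neighbour ring and at least one background axial neighbour) among
staircase leftovers and two-pixel braids. Endpoints are never deleted and
clean two-neighbour corners are kept, so minimal digital lines and cycles
survive. The output has no 2×2 block, its support is a subset of the input
mask, and the number of connected components is preserved.

**Border clearing.** Skeleton pixels within `margin_px` (default 10) of the
frame are discarded: edge detectors produce frame artifacts, and segments
touching the border have truncated geometry.

**Graph tracing.** Pixel degree is computed in 8-connectivity: degree-1
pixels are endpoints, degree ≥ 3 pixels are junction pixels, and 8-adjacent
junction pixels merge into one junction node (a raster crossing is a small
cluster, not a single pixel). Segments are maximal degree-2 chains between
nodes, categorized as endpoint-to-endpoint, junction-to-endpoint,
junction-to-junction, or isolated cycle. Traced paths include endpoint
pixels but exclude junction pixels, so lengths are measured over the chain
itself; direct node–node contacts are zero-length artifacts and are
dropped, as are isolated single pixels. Two-pixel segments are valid.

**Path length and the staircase problem.** A digital 8-connected path
overestimates the length of the underlying smooth curve when measured by
chain code (1 per axial step, $\sqrt 2$ per diagonal step) — by up to ~8%
for lines near 22.5° off-axis. That bias would leak straight into
tortuosity, which must be exactly 1 for straight fibers *at any angle*. We
therefore measure $c$ as the arc length of the traced path after a centred
moving-average smoothing (`smooth_window_px = 5`, endpoints fixed, circular
for cycles). Collinear equally spaced pixels are invariant under the moving
average, so axis-aligned and perfect-diagonal paths keep their exact
chain-code lengths; curved paths lose the raster jitter but, at 5 px against
the 50 px+ wavelengths of interest, essentially none of their true
curvature. Setting `smooth_window_px = 1` restores the raw chain-code sum.

**Filtering.** A segment is excluded iff $c <$ `min_length_um` (default
100 µm) *or* $d <$ `min_chord_um` (default 50 µm). Isolated cycles have
$d = 0$ and are therefore always removed under the defaults. Raising either
threshold can only shrink the surviving set.

**Orientation statistics.** Chord angles are folded to $[0,\pi)$ because
segments are undirected. The fold is deliberately *not* wrap-invariant: a
bundle oriented near the 0/π seam splits into values near 0 and near π and
inflates the SD/IQR. `recenter_axial = TRUE` first rotates angles by the
axial (doubled-angle) circular mean, making the dispersion seam-independent;
it is off by default so that the plain folded statistics are what the
biomarkers report. The built-in cohorts use a base angle of 1.2 rad, safely
away from the seam.

## Group comparison

`anova_oneway()` implements the classical between/within mean-square ratio
with $p$ from the $F(k-1, N-k)$ distribution. `tukey_kramer()` forms
$q = |\bar y_i - \bar y_j| / \sqrt{\mathrm{MSW}\,(1/n_i + 1/n_j)/2}$ and
refers it to the studentized range distribution with $k$ means and $N-k$
df (base R's `ptukey`, a vetted special-function routine; for balanced
groups the SE reduces to $\sqrt{\mathrm{MSW}/n}$). Printed reports use the
conventional asterisk tiers at 0.05 / 0.01 / 0.001 / 0.0001. Rows of the
results table are the experimental units; no multiplicity correction is
applied across biomarkers.

## The synthetic verification surface

Real confocal datasets of regenerating muscle are not publicly deposited, so
verification rests on a generator whose ground truth is known analytically.
`generate_scene()` renders fibers as bright Gaussian-profile ridges (peak 1,
cross-section σ = 2 px) over a dark background by splatting kernels along
sampled centerlines (0.5 px spacing):

* centerline $=$ straight line at angle base ± uniform jitter, plus a
  sinusoidal displacement of amplitude $a$ and period $\lambda$ with random
  phase — for whole-period fibers the analytic tortuosity is
  `sine_tortuosity(a, lambda, L)`, an adaptive quadrature of
  $\sqrt{1 + (2\pi a/\lambda)^2 \cos^2(2\pi x/\lambda)}$ that two
  independent numerical routes (quadrature vs dense polyline summation)
  agree on to 1e-6;
* optional branch events diverging at a set angle from a random point
  (probability `split_prob` per fiber);
* multiplicative dark elliptical occluders emulate the shadow artifacts
  that contaminate real micrographs — they are a documented failure mode,
  expected to make tortuosity noisier, not a condition under which accuracy
  is promised;
* additive Gaussian noise, then clipping to $[0,1]$. Overlapping fibers
  merge additively, mimicking touching fibers with low mutual contrast.

Scenes are deterministic given the seed, and the caller's RNG stream is
left untouched. Ground truth records each centerline polyline in µm, its
arc/chord tortuosity, chord orientation, length and clipping flag, plus all
split events.

Three cohort profiles fix the study conditions (384 × 384 px at 2 µm/px;
14 fibers; base angle 1.2 rad; noise SD 0.02): `acute_like` (jitter 0.04
rad, no waviness, no splits, 450 µm fibers), `chronic_like` (jitter 0.45
rad, $a = 7$ µm at $\lambda = 120$ µm, split probability 0.5, 200 µm
fibers) and `treated_like` (intermediate: jitter 0.20 rad, $a = 3$ µm,
split probability 0.2, 320 µm fibers). These were chosen once, from the
qualitative descriptions of acute injuries, saline-treated ulcers and
DFO-treated ulcers, and are not tuned: the acceptance checks ask only for
the *direction* of the group contrasts (higher orientation IQR, shorter
segment distance in `chronic_like`), not for particular p-values.

What the generator does **not** emulate: confocal point-spread functions,
multi-fluorophore lineage colour, intensity vignetting, tile-scan stitching
seams, and densely packed tissue where fibers touch over long runs. Passing
tests on these phantoms therefore demonstrate that the measurement chain is
correct, not that any particular detector performs well on real tissue.

## Numerical choices and degenerate inputs

* Double-threshold boundaries are intermediate (`tl <= I <= th`), matching
  the strict inequalities for strong/weak.
* Bilinear samples falling outside the frame are ignored in NMS
  comparisons; constant orientation regions default to angle 0.
* IQR uses linear percentile interpolation (R type 7); SD uses the
  population ($n$) divisor.
* Cycles ($d = 0$) make tortuosity and orientation undefined; they are
  skipped in aggregation, never imputed. Images with zero usable segments
  report `NA` statistics with `n_segments = 0`.
* A constant image produces an all-zero probability map and an empty result
  rather than an error; a non-finite pixel aborts with the failing stage
  named.
* `anova_oneway()` refuses groups with fewer than 2 observations and
  all-identical data; zero within-group variance with non-zero between
  yields $F = \infty$, $p = 0$.

## Problem sizes

The shipped verification suite runs, per check: 200 random 64 × 64
labelings against a flood-fill oracle; 100 random three-group datasets
(n = 6 per group) against `aov`/`TukeyHSD`; 5000 null simulations for the
type-I error rate; 20 replicate two-arm cohorts of 6 + 6 synthetic images
(384 × 384 px) for the directional contrast; and single scenes for the
tortuosity, NMS-thinness and invariance checks. These sizes give stable
pass/fail behaviour at desk scale while keeping a full run in the tens of
minutes.

## Known limitations

* Tortuosity is measured per *edge segment*, not per biological fiber; a
  fiber whose edge is interrupted (by a crossing, a shadow, or a detection
  gap) contributes several shorter segments.
* The micron filters interact with calibration: the same scene analysed at
  a different `pixel_size_um` keeps its tortuosity and angle statistics but
  can change which segments survive, because the filters are physical.
* Shadows reliably induce spurious junctions and shortened segments; the
  median-based biomarkers damp but do not remove this.
* The folded-angle IQR is seam-sensitive by design (see above); use
  `recenter_axial = TRUE` for seam-independent dispersion.
* Only single-plane 2-D analysis is supported; z-stacks must be projected
  upstream.
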