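---
title: "germquant: models, scoring rules and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{germquant: models, scoring rules and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`germquant` quantifies spore germination in *Schizosaccharomyces pombe*
timelapse microscopy. This vignette is the package's account of the
measurement model, the scoring rules and their parameters, the synthetic
data the tests rely on, and the design choices that were genuinely open.

## The measurement model

Every segmented object in every frame is summarized by the ellipse with
the same normalized second central moments as its pixel set (axes
$4\sqrt{\lambda_i}$, the standard moments-matching ellipse used by common
region-properties implementations). The **aspect ratio** (AR) is the
ratio of the long to the short axis of that ellipse; a circle has AR 1.
Each pixel contributes as a unit square, which adds $p^2/12$ ($p$ = pixel
size) to both eigenvalues; for regions larger than a few dozen pixels the
effect is negligible, and for degenerate collinear regions it floors the
minor axis at roughly one pixel width instead of producing an infinite
ratio (such regions are additionally flagged).

Coordinates use 0-based pixel indices with centroids at
$(\text{index} + 0.5)\,p$ micrometres; frame $k$ (0-based) is at time
$k \cdot \Delta t$ with $\Delta t = 10$ min by default, so frame 0 is
time point zero. Pixel size is not carried in the TIFF files and must be
supplied; the default 0.18 µm/px corresponds to a 60× objective with an
11-µm-pixel camera, and makes the micrometre-scale thresholds meaningful.

## Scoring rules and their parameters

| parameter | default | meaning |
|---|---|---|
| `spore_ar_max` | 1.4 | gate: objects with AR < 1.4 (strict) at frame 0 are circular, hence likely spores |
| `division_ar` | 3.0 | first division = first frame with raw AR > 3.0 (strict) |
| `elongated_cutoff_um` | 6 | outgrowth protrusion above which a cell is scored elongated |
| `focus_loss_max_frames` | 5 | more than 5 flagged frames exclude the timelapse |
| `smoothing_window_frames` | 3 | centered moving average for swelling detection |
| `swelling_area_eps` | 0.01 | relative area slope per frame that counts as growth |
| `swelling_ar_eps` | 0.02 | absolute AR slope per frame still counted as "no AR increase" |
| `bubble_ar_max` | 1.6 | a split while AR is below this is a bubble division |
| `explode_area_drop_frac` | 0.5 | area loss within two frames that marks an explosion |
| `bipolar_min_protrusion_um` | 1.5 | per-pole protrusion (tube radius + 0.5 µm) for a bipolar call |

All boundary comparisons are strict as stated: AR 1.40 at time zero is
rejected by the gate, AR exactly 3.0 does not call a division.

**Division calling** uses the raw AR series, not the smoothed one.
Focus-gap rows filled by interpolation may carry the series, but a
crossing supported only by an interpolated row is deferred to the next
measured frame, so artifact frames cannot create divisions. Bubbles never
reach AR 3 — they divide while still circular — so their division is read
from the tracking split event instead (a one-parent → two-daughter event
with conserved area), at the split frame.

**Outgrowth classification** is evaluated at the frame before the first
division (or the last frame for non-dividers). The spore body is modelled
as a disc of the time-zero radius at the time-zero centroid; the
protrusion on each side is the farthest mask pixel beyond that disc along
the major axis. Priority order: exploded, bubble, bipolar, elongated,
normal — so a spore that is both bipolar and elongated is counted
bipolar. The protrusion length is recorded so users can re-bin with a
different cutoff.

**Swelling** is an increase in area without an increase in AR. Since the
published definition does not fix the window endpoints operationally, the
package uses a slope rule on the smoothed series: the window is the
longest run (of at least two slope steps) where the relative area slope
exceeds `swelling_area_eps` while |ΔAR| stays within `swelling_ar_eps`.

**Vacuole partitioning** splits a germinating cell into the spore body —
a disc of the time-zero radius placed at the round-end pole — and the
outgrowth, then computes background-subtracted intensity sums (per-frame
median outside all cell masks; negative residuals clamped at zero). The
fraction is a ratio, so it is exactly invariant to any positive intensity
rescaling, and body + outgrowth fractions sum to one by construction.
Two half-pixel raster conventions matter at this size scale and are
applied symmetrically: the round-end extreme *pixel centre* lies about
half a pixel inside the continuous outline (the disc centre is pulled
back by $p/2$), and disc membership counts pixels whose unit square
overlaps the disc (radius + $p/2$). Without them the estimator carries a
systematic ~0.04 deficit in the body fraction.

**Statistics.** CFU series are normalized to their day-0 count; survival
curves are compared by a two-sided two-sample t-test on per-replicate
trapezoidal AUCs (Student's pooled test by default, Welch optional;
degenerate zero-variance groups are floored at machine epsilon so that
identical groups give p = 1). Whether the published comparisons
integrated replicate curves or the mean curve is not stated; AUC per
replicate followed by a t-test is this package's definition, consistent
with the replicate counts reported alongside. Fisher's exact test is
two-sided by probability ordering — the sum of hypergeometric
probabilities of all tables with the observed margins no more probable
than the observed table, with the conventional $1 + 10^{-7}$ relative
slack for floating-point ties (other two-sided conventions exist). The
one-way ANOVA is the classical fixed-effects F test; for two groups
F = t² exactly. No multiple-testing correction is applied by default, to
match per-comparison reporting; `p.adjust` can always be applied to the
returned p-values.

## The synthetic timelapse generator

The generator emulates what the analysis assumes about germinating
spores trapped under an agar pad, with a complete per-cell ground truth.

* **Geometry.** A cell is a disc body of radius $R$ plus a capsule germ
  tube of radius $r_t$ protruding $L$ beyond the body boundary (both
  poles for bipolar cells). Because the shape is symmetric about the tube
  axis, its area, centroid and second moments reduce to one-dimensional
  integrals of the half-width profile, evaluated with fixed-order
  Gauss–Legendre quadrature — closed-form for practical purposes and
  completely independent of the renderer. These analytic moments are the
  ground truth that rasterized measurements are tested against.
* **Kinematics.** Dormant spores are circles of true area ≈ 7–9 µm²
  (radius 1.55 ± 0.10 µm). After a gamma-distributed lag (mean 240 min,
  sd 60 min) the cell swells isotropically (+40 % area over 120 min, AR
  flat), then grows a tube at 0.25 µm/frame. The **true division frame**
  of every tube-growing cell is the first frame its analytic AR reaches
  3 — the same rule the analysis applies — so detector and truth are
  commensurable by construction.
* **Tube width and division length.** With the swollen body, the
  moment-ellipse AR reaches 3 at ≈ 4.7 µm of outgrowth when the tube is
  2.0 µm wide; that pair (germ tubes narrower than the ~3.5 µm mature
  cell) reproduces the observed ~4.5 µm outgrowth at division together
  with AR ≈ 3 at division. No width makes an AR-3 division happen at
  exactly 4.5 µm for this body size, and a 3.3-µm tube would not divide
  until ≈ 6.6 µm — past the elongated cutoff — so 2.0 µm is the
  self-consistent default. Elongated (cell-cycle-defective) cells draw a
  division length uniformly in 7–20 µm and their tube width is solved per
  cell so the AR-3 crossing lands at that length; these cells come out
  wide as well as long. Wide tubes emerge gradually (effective radius
  $\min(r_t, 0.9R + L/2)$) so the mask has no non-physical area jumps.
* **Aberrant classes.** Bubbles keep growing isotropically
  (+1.5 % area/frame) and split through the middle while still circular;
  bipolar cells grow tubes from both poles and divide at the AR-3
  crossing; exploded cells fragment into four sub-resolution pieces
  partway through outgrowth and vanish two frames later; dead spores
  never change. Debris are static elongated blobs (AR 1.8–3, 3.5–8 µm²)
  that the time-zero gate must reject.
* **Rendering.** Cells are bright smooth objects on a dark background
  (contrast polarity is configurable downstream) with Gaussian blur
  (σ = 0.6 px) and additive Gaussian noise (σ = 0.02 on a [0, 1] scale).
  Division is rendered as a septum gap of 2 px (0.36 µm — a realistic
  septal constriction that remains resolvable after the blur; a 1-px gap
  closes under blur and merges the daughters) appearing 3 frames after
  the AR-3 crossing, so the parent is still one object when its AR
  crosses the threshold, as in real images where the constriction lags
  the shape change. Focus-loss frames are rendered with σ = 6 px blur.
  Cells do not move (spores are trapped under the agar); optional ≤ 1 px
  jitter exists for tracking tests.
* **Dye channel.** In two-channel mode each cell's channel-2 intensity is
  split between body and outgrowth at its drawn body fraction, exactly
  before noise (per-pixel values are rescaled jointly if they would
  clip, which leaves the fraction untouched). Cells start pre-germinated
  in this mode, mirroring a protocol where spores germinate in liquid
  for ~270 min and are stained for 30 min before imaging; the dye channel
  shares the transmitted-light frame grid (a 15-min channel interval can
  be emulated by sub-sampling).
* **Composition.** Phenotypes are drawn multinomially from
  `phenotype_mix`; `phenotype_counts` instead fixes the per-class counts
  exactly (positions still randomized). Exact composition is what a
  "population with viability 0.70" means for recovery checks: with
  multinomial draws the true viable fraction itself fluctuates
  binomially, and no detector could track the nominal value more tightly
  than that sampling noise.
* **Determinism.** One RNG stream per scene: per-cell draws in cell-ID
  order, then debris, then placement (capsule rejection sampling with a
  segment-distance overlap test), then per-frame image noise. Identical
  seeds give bit-identical images, masks and truth, and the truth does
  not depend on whether the intensity image is rendered.

What the generator does **not** model: bright-halo/dark-interior optics
of real transmitted-light spores, uneven illumination, cell motion,
segmentation errors of a learned model, overlapping or touching spores at
time zero, second divisions, or dye-uptake kinetics. Passing tests
therefore demonstrate that the scoring rules recover known geometry and
kinetics from realistic rasterized masks and images — not that any
particular segmenter is accurate on real micrographs; for real data the
mask-import adapter exists precisely so a learned segmenter can stand in
front of the same analysis.

A manual-audit hook (`writeAuditMontages`, or `phenotype --audit`)
writes per-track image strips for a random sample of at least 30 gated
cells, mirroring manual confirmation of algorithm outputs; it is a
report for a reviewer, never a pipeline gate.

## Numerical choices

* Otsu's threshold is computed per frame on the [0, 1]-rescaled image; a
  constant frame yields an empty labelling rather than an error.
* Touching objects are separated only where a background (septum) line
  survives thresholding; no distance-map watershed is applied, keeping
  the mask contract deterministic.
* Greedy nearest-centroid linking (not globally optimal): spores are
  motionless, so global assignment would add complexity without benefit.
  Ties break by smallest relative area change, then lowest label. A link
  is refused when the relative area change exceeds 0.45 — a halving
  object is a division, not a displacement — which is what makes the
  split event visible. The split search radius scales with the parent's
  major axis, since the daughters of a long cell sit half its length
  from the parent centroid.
* Focus-loss sharpness is the variance of the gradient magnitude of a
  lightly smoothed (σ = 1 px) copy of each frame; the smoothing keeps
  sensor noise from masking the loss of edge content. A frame is flagged
  below median − 3·MAD across frames.
* The `maxGap` allowance (2 frames) governs ordinary gaps; frames
  excluded as focus losses are dropped before linking and do not count
  against it.

## Problem sizes in the tests

The packaged checks run the full pipeline at population scale: a 200-cell
mixed-phenotype scene for division-call recall, 20 independent 300-cell
scenes for germination-efficiency coverage, a 250-cell balanced scene for
the five-class confusion, 100 two-channel cells for vacuole recovery, an
exhaustive Fisher sweep over all 2×2 tables with margins up to 30
(162,315 tables), and 200 + 1,000 seeded CFU simulations for the power
and size of the longevity comparison. These sizes keep every estimate's
Monte-Carlo error well inside the tolerance it is tested at.

## Known limitations

* The classical segmenter assumes a single contrast polarity and roughly
  uniform background; real micrographs with halos need the mask-import
  path.
* Only the first division is modelled and scored; no lineages.
* The exploded call depends on fragment visibility or a disappearance
  heuristic; with an aggressive minimum-area filter, explosions reduce
  to disappearances.
* Vacuole quantification assumes co-registered channels (single-camera
  acquisition) and evaluates one frame before division; after the split
  the outgrowth is a separate label and the partition is no longer
  defined.
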