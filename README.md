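# germquant

Quantitative phenotyping of fission-yeast (*Schizosaccharomyces pombe*)
spore germination from transmitted-light timelapse microscopy.

Spores germinating on solid media are imaged every 10 minutes for at least
1,000 minutes. `germquant` turns such a timelapse into per-spore
germination phenotypes:

* **Segmentation** of each frame into labelled objects — a classical
  threshold-plus-morphology segmenter is included, and label masks produced
  by an external (e.g. learned) segmenter can be imported through the same
  container, with identical downstream behaviour.
* **Morphometrics**: each object is summarized by the moment-matching
  ellipse of its pixel set. The **aspect ratio (AR)** is the ratio of the
  long to the short axis of that ellipse; areas are in μm².
* **Tracking**: greedy nearest-centroid linking of the essentially
  motionless spores, with gap interpolation and detection of one-parent →
  two-daughter split events.
* **Scoring rules**: objects with AR < 1.4 at time point zero are gated as
  spores; the **first division** of a gated spore is the first frame its
  raw AR exceeds 3.0 (division time = frame × 10 min); **swelling** is a
  window where area rises while AR does not; **germination efficiency** is
  the fraction of gated spores that divide before the end of the
  timelapse; each outgrowth is classified as **normal**, **elongated**
  (protrusion > 6 μm), **bubble** (divides while still circular),
  **bipolar** (grows from both poles; a spore that is both bipolar and
  elongated counts as bipolar), or **exploded** (disintegrates).
* **Vacuole asymmetry**: with a second fluorescence channel (vacuole dye),
  the fraction of total cell signal retained in the spore body versus the
  germ-tube outgrowth at the first division.
* **Statistics** for the accompanying plate assays: CFU survival curves
  normalized to day zero and compared by t-test on per-replicate
  trapezoidal AUCs; Fisher's exact test (two-sided, probability ordering)
  on germinated fractions; one-way ANOVA on division times; percent
  survival after acute stress.
* A **synthetic timelapse generator** with closed-form kinematic ground
  truth (per-cell phenotype, division frame, vacuole fraction), used by the
  test suite so every stage is verifiable without microscope data.

Frames where autofocus failed are detected from a per-frame sharpness
statistic; a timelapse with more than 5 such frames is excluded, shorter
focus gaps are interpolated and flagged.

## Worked example

```r
library(germquant)

# a synthetic field of 20 spores with mixed phenotypes, imaged for 1000 min
scen <- scenarioConfig(n_spores = 20, n_debris = 4, seed = 42)
sim  <- simulateScene(scen)           # image + truth masks + ground truth

masks <- segmentStack(sim$image)      # or loadExternalMasks("learned_masks.tif")
meas  <- measureAll(masks)
ts    <- linkTracks(meas, nFramesTotal = nFrames(masks),
                    pixelSizeUm = pixelSize(masks))
calls <- phenotypeTracks(ts, masks)
germinationEfficiency(calls)
table(calls$phenotype[calls$is_spore])
```

Output on this scene:

```
$efficiency
[1] 0.85

$n_divided
[1] 17

$n_spores
[1] 20

  bipolar    bubble elongated  exploded      none    normal
        1         4         3         1         2         9
```

17 of the 20 gated spores complete a first division (the `none` calls are
the dead spores, and the exploded spore never divides), with a warning
that 20 spores is below the more-than-50-per-sample reporting convention.
The phenotype table matches the generator's drawn mix exactly.
Division times are in `calls$division_time_min`; per-frame population
means of area and AR come from `populationCurves(ts)`.

A thin command-line wrapper mirrors the same steps
(`inst/scripts/germquant.R`):

```sh
Rscript inst/scripts/germquant.R simulate --scenario scen.yaml --seed 7 --out run/
Rscript inst/scripts/germquant.R segment  --in run/stack.tif --out run/seg.tif
Rscript inst/scripts/germquant.R track    --masks run/masks.tif --out run/tracks.csv
Rscript inst/scripts/germquant.R phenotype --tracks run/tracks.csv \
        --masks run/masks.tif --out run/calls.csv
```

Every subcommand logs its parameters, writes a JSON manifest, and is
byte-reproducible under a fixed `--seed`.

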