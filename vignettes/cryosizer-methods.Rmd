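---
title: "Methods: automated detection and sizing of vesicles and lipoproteins in cryo-EM micrographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated detection and sizing of vesicles and lipoproteins in cryo-EM micrographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryosizer)
```

## The problem

Extracellular vesicles (EVs) are lipid-bilayer-delimited particles released
by cells. In defocused bright-field cryo-EM (underfocus of a few
micrometres), the two leaflets of the bilayer appear as a pair of dark
fringes roughly 4 nm apart, which makes the bilayer ring the defining image
feature of an EV. Blood- and medium-derived EV preparations co-isolate
lipoproteins — HDL (~7–12 nm), LDL (~18–25 nm) and VLDL (~30–70 nm) — and
exomere-like dense particles (~45 nm), none of which have a bilayer: they
appear as filled dark discs. Surface-ice contamination shows up as
irregular high-contrast blobs, and the rim of the 2 µm hole in the carbon
support foil is a curved dark band that mimics a bilayer in projection —
the canonical false positive.

`cryosizer` implements the automated analysis chain for such data:
per-pixel segmentation of the structure classes, ring detection by a Hough
circle transform, particle sizing, artifact exclusion, and
size-distribution statistics — together with a synthetic micrograph
simulator that provides exact ground truth, so that every stage of the
chain is testable without microscope data.

## The simulator

`scene_spec()` + `simulate_micrograph()` generate seeded synthetic fields
that emulate the imaging conditions the pipeline targets: 0.55 nm pixels at
the specimen level, a total dose of ~32 e/Å² (4 e/Å²/s × 8 s), one 2 µm
carbon hole whose rim may clip the field of view. Particles are darker than
the background (the sign convention of defocused bright-field contrast; sign
errors are the classic failure mode, so the convention is fixed and tested).

Per class, the radial contrast profile is phenomenological:

* **EV bilayer** — two Gaussian intensity dips of half-width ~1 nm at radii
  $r \pm s/2$, with leaflet separation $s = 4$ nm. The ring midline is the
  measured quantity: the true diameter of a simulated vesicle is the
  diameter of that midline circle.
* **Dense particles** (HDL/LDL/VLDL/small dense) — a filled disc, darkest
  at the centre, with a ~1 nm logistic edge at $\rho = d/2$; the footprint
  (attenuation above half depth) therefore has area $\pi (d/2)^2$, so the
  area-equivalent diameter formula recovers $d$ ("physical honesty", tested
  to within 2 pixels' worth of nm).
* **Ice** — a union of 3–6 jittered sub-discs, giving an irregular
  high-contrast silhouette.
* **Hole rim** — a dark band of ~8 nm width along a 2 µm circle anchored at
  a random border point of the field.

Default diameter distributions are lognormal(median 60 nm, σ~log~ 0.3) for
EVs (the spread typical of small-EV preparations), normal(45, 4.5) nm for
exomere-like particles, and the class ranges above for lipoproteins.
Contrast depths default to 40 grey levels for bilayers and 35 for dense
particles on a background of 150 — with the shot-noise model below this is a
high-contrast (aligned-movie, DED-quality) setting; lowering `depth` towards
the noise floor emulates harder (CCD-like) data. No quantitative contrast
calibration is claimed: depths are free parameters of the simulator.

Shot noise is a Gaussian approximation to Poisson counting noise: with
$N = \text{dose} \times a^2$ electrons per pixel (pixel size $a$ in Å), the
relative SD is $1/\sqrt{N}$, so variance scales as 1/dose (tested).
Ice-thickness variation is a smooth low-order background modulation with
amplitude 5% of the background by default. Counts per class are
Poisson(density × field area); placement rejects centroid pairs closer than
half the sum of radii (100 retries, then an overcrowding error). With
`placement = "interior"` particles are placed wholly inside the field —
the right choice for size-recovery experiments, because border-clipped
particles are excluded from sizing downstream and clipping preferentially
removes large particles: at desk-scale fields this selection alone biases
the detectable-sample median by about −1 nm, an artifact of the small field
rather than of the sizing chain (in the emulated protocol a full 2 µm hole
is imaged, where clipping is negligible).

What the simulator does **not** model: the contrast transfer function and
its defocus-dependent fringes, beam-induced motion, radiation damage,
crowded/overlapping particle fields, multilamellar and tubular vesicle
morphologies, and real vitreous-ice texture. Passing the simulation suite
therefore demonstrates the correctness of the *computational chain*
(segmentation → outlines → Hough → sizing → statistics), not
detector-grade performance on real micrographs.

## Preprocessing

Four conditioning steps, matching the order of use in the workflow:

* `normalize_to_8bit()` — percentile clip (default 0.1/99.9) and linear map
  to [0, 255]. A constant image yields flat mid-grey with a warning.
* `bandpass_filter()` — a radially symmetric Gaussian band mask in the
  frequency domain, parameterized by structure sizes: the default band
  passes feature sizes between `filter_small = 2` and `filter_large = 50`
  pixels. The transfer function is
  $H(f) = e^{-(c\,s f)^2/2}\,(1 - e^{-(c\,L f)^2/2})$ with sharpness
  $c = 2.2$ chosen so that sizes at the band edges are attenuated by ≥90%
  while the geometric mid-band keeps ≥80% amplitude; DC is removed exactly
  and the output has mean ~0. Bit-exact replication of any particular
  plugin implementation is a non-goal; the attenuation/preservation bounds
  *are* the compatibility contract, and the tests enforce them via an
  independent amplitude-measurement oracle.
* `bin_image()` — mean pooling (preserves SNR and the image mean exactly),
  cropping to multiples of the factor; 4× binning takes 0.55 nm pixels to
  the 2.2 nm working resolution of the sizing stage.
* `despeckle()` — a 3×3 median filter (replicated borders), removing
  isolated false-positive pixels from prediction masks while leaving solid
  interiors untouched.

Bandpass filtering is applied before training/predicting the lipoprotein
and ice models, whose contrast sits on strong ice-thickness background
variation, but **not** before the bilayer model — the bilayer path works on
unfiltered images. The preprocessing signature is recorded in each trained
model and checked at prediction time so the two paths cannot be mixed up
silently.

## Per-pixel segmentation

One independent binary model per structure class, as in per-class
supervised segmentation generally: overlapping predictions from different
class models are allowed and resolved downstream (no cross-model
non-maximum suppression). Training data come from rectangular ROI boxes
with per-pixel labels (`annotation_set()`); boxes larger than the patch
size are tiled. `annotation_stats()` reports the provenance arithmetic
(number of ROIs, fraction of total image area, per-class pixel counts) as
a computable report.

The classifier is a one-hidden-layer MLP (default width 8) over a
multi-scale rotation-invariant filter bank: mean-centred intensity,
Gaussian means at scales {1, 2, 4} px, differences of Gaussians, gradient
magnitude, and local SD — the pixel-classification design of ilastik/Weka-
style tools, chosen because it trains in seconds on one CPU and its
failure modes are interpretable. Two deliberate choices:

* **No per-image variance scaling.** Features are intensity-centred but not
  rescaled per image: the absolute contrast of a structure against the
  background is the discriminative signal. Per-image standardization would
  amplify blank-field noise into apparent structure (we measured a ~30%
  false-positive rate on blank fields with per-image scaling, ~0 without).
  The cost is that training and prediction images must share one intensity
  calibration, which the pipeline's normalization stage provides.
* **No elastic augmentation.** The filter bank is rotation-invariant by
  construction, so dihedral augmentation is available but off by default,
  and elastic deformation is excluded because it would distort the 4 nm
  leaflet separation that defines the bilayer class.

Training is fully seeded (initialization, pixel subsampling, minibatch
order), uses class-balanced sampling of up to 20 000 pixels, minibatch Adam
on binary cross-entropy, and logs per-epoch loss; a non-finite loss raises
an error naming the epoch. Models serialize to plain JSON with the class
name, preprocessing signature and training configuration as a sidecar.
Prediction can run whole-image or in tiles with a context halo; the halo
makes tile seams invisible (tested: probability discontinuity < 0.05).

Specificity of the bilayer model — the behaviour that VLDL and other dense
particles are *not* detected — is achieved by training on mixed synthetic
fields in which only bilayer pixels are positive, so dense discs enter as
hard negatives. The tests verify blank-field and VLDL-only positive-pixel
rates under 1% while vesicle rings are covered.

## The classical ring detector

`classical_bilayer_detector()` is a deterministic baseline that decouples
the sizing chain from stochastic training: a matched filter correlating the
(background-subtracted) image with zero-mean, unit-norm double-leaflet ring
templates over a radius sweep. Peaks above an SNR threshold (default 6
noise SDs) pass non-maximum suppression, then each accepted ring must pass
a **shell-contrast test**: the mean intensity on the annulus must be at
least `lumen_k = 2` noise SDs darker than both the inner shell (towards
the lumen) and the outer shell. A bilayer is a thin dark *line* with
background-level intensity on both sides; a filled disc is dark on one
side of its edge and fails — this test is what makes the detector
bilayer-specific (VLDL-only fields produce empty masks in the tests).
Accepted rings contribute their annulus intersected with the dark-pixel
set, so partially rendered rings yield partial arcs for the Hough stage.
Known limitation: tightly nested multilamellar rings suppress each other's
shells; the Hough stage's suppression rule, not the detector, is what
preserves concentric rings when they are present in a mask.

## Hough circle transform and sizing

`mask_to_outlines()` reduces masks to outlines: boundary pixels (edge mode,
for filled particle segmentations) or Zhang–Suen 1-px skeletons (for ring-
shaped bilayer segmentations) — a filled disc gives one closed boundary, an
annulus one closed ring.

`hough_circles()` votes every outline pixel into a (y, x, r) accumulator
over radii 6–100 px by default. Rasterization is the midpoint-style integer
circle (union of both axis sweeps of rounded circle points); the score of a
candidate is its votes divided by the perimeter count of the ideal
rasterized circle at that radius, so a complete ideal ring scores exactly 1
and an arc covering a fraction α of the circle scores ≈ α. Score
thresholds: 0.8 for complete circles, 0.5 for rings — the ring threshold is
what buys detection of incomplete circles. At the 2.2 nm binned pixel the
radius sweep of 6–100 px corresponds to reportable diameters of 26.4–440 nm
(`d = 2 r · 2.2`); note that the nm bounds are *diameters* while the pixel
bounds are *radii* (6 px radius = 13.2 nm radius = 26.4 nm diameter), a
unit reconciliation this package states explicitly rather than silently
reinterpreting. No sub-pixel refinement is attempted: radius resolution is
1 px = 2.2 nm at default binning, so reported diameters live on a 4.4 nm
grid, and a sample median will snap to that grid.

Non-maximum suppression processes candidates in descending score (ties:
smaller radius, then raster order); a candidate is suppressed when its
centre is within max(r₁, r₂)/2 of an accepted peak **and** radii differ by
less than 25%. Both clauses are needed: concentric rings of multilamellar
vesicles share a centre but differ in radius (kept), near-duplicate
accumulator peaks share both (dropped). The fast accumulator (C++ scatter)
is verified against an independent pure-R gather-style oracle to 1e-9 on
random outline images.

Filled-particle sizing uses 8-connected components (`component_records()`)
and the area-equivalent diameter $d = 2\sqrt{A/\pi}$, which applies to oval
particles as well; touching particles merge into one component — a known
limitation of surface-based sizing, documented rather than patched.

`exclude_artifacts()` flags (never deletes) records: carbon-hole-rim
detections (concentric with the rim, osculating it, or with a large on-rim
perimeter fraction — the fraction threshold is derived from the tangency
geometry $\arccos(1 - \mathrm{tol}/r)/\pi$ rather than fixed), border-
truncated records, and records overlapping the ice mask. `size_distribution()`
reports median, sample SD (n−1; a single particle reports SD 0 with a
flag), count, and a histogram with half-open [lo, hi) bins of 10 nm default
width.

## Evaluation

`match_particles()` performs greedy one-to-one matching in descending
prediction score; a pair is valid when the centroid distance is at most
max(5 px, half the true radius) and the relative radius error is at most
25%. Precision, recall and F1 follow their standard definitions. Because a
detection task has no true negatives, "accuracy" is ambiguous; this package
defines accuracy = tp/(tp + fp + fn) (a Jaccard-style index) and always
reports it alongside precision/recall/F1 so results are interpretable
regardless of which convention a reader assumes. A seeded image-subset mode
(`evaluate_subset()`) mirrors the protocol of visually inspecting a fixed
fraction of a large dataset.

## The pipeline driver and reproducibility

`run_pipeline()` ties the stages together into a flat run directory with
standard formats only (MRC images with the pixel size in the header, PNG
masks, CSV records, JSON metrics/distributions, YAML config). Every stage
is content-addressed by the hash of its configuration plus its upstream
hash; re-running an unchanged configuration skips completed stages, and
because downstream stages always consume the *reloaded* stage outputs,
skipped and recomputed runs are byte-identical. One global seed determines
the simulate and detect outputs completely. nm is the single physical unit
at all interfaces; conversions (Å in MRC headers) happen only at file
boundaries. A thin command-line front end (`inst/cli/cryosizer`) exposes
the same stages as subcommands.

## Problem sizes used by the test-suite experiments

The size-recovery experiment simulates 50 micrographs of 1152×1152 px at
0.55 nm/px (a 0.63 µm field), EV density 30/µm² with lognormal(60 nm, 0.3)
diameters placed interior, VLDL confounders at 2/µm², a hole rim, dose
32 e/Å², and runs 4× binning → ring detection → despeckle → skeleton →
Hough (radii 6–40 px, ring threshold 0.5) → artifact exclusion. The density
gives ~580 detected vesicles, at which the asymptotic SE of a lognormal
sample median ($m\,\sigma_{\log}\sqrt{\pi/2}/\sqrt{n}$ ≈ 1.1 nm) makes the
±5% recovery band a comfortable multiple of the sampling noise — a power
calculation, not a tuned value. Classifier experiments use 256 px fields at
the binned 2.2 nm pixel with ~200 training patches. These sizes are the
package's desk-scale study design; all of them are parameters, not limits.

## Numerical choices and degenerate inputs

* Coordinates are 1-based (row, col) = (y, x), matching R matrices; radii
  are in pixels internally and converted to nm only in records.
* FFT convolutions use periodic boundary; the pixel classifier's tiled
  prediction re-centres tiles with the whole-image mean so seams vanish.
* Constant images: `normalize_to_8bit` warns and returns mid-grey;
  `bandpass_filter` returns ~0.
* Degenerate particles (diameter < 2 px) are an error in profile rendering;
  vesicles whose inner leaflet would sit within 2σ of the centre are
  rendered but flagged `leaflet_resolved = FALSE`.
* Empty masks/outlines propagate as empty record tables, and an empty
  record set yields a size distribution with count 0 and a flagged,
  undefined median rather than NaN.
* Ties in Hough NMS are broken by smaller radius, then raster order, making
  detection order fully deterministic.

## Known limitations

Sizes are 2-D projections: no correction for flattening of large vesicles
(>200 nm) in thin ice is attempted. Touching filled particles merge under
area-based sizing. The classical detector suppresses tightly nested
multilamellar rings. The simulator's contrast model is phenomenological —
results on synthetic scenes bound what the code does, not what any
microscope will deliver. Lipoprotein contrast values are free simulator
parameters, uncalibrated against real data.
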