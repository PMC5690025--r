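---
title: "Methods: synthetic phantom QA, texture-based artifact detection, and Winston-Lutz analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic phantom QA and artifact detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

phantomiq automates the analysis side of routine imaging QA for linac
on-board imagers. Three things make that possible without a machine or a
physical phantom: a seeded digital phantom whose geometry is known exactly, a
feature battery rich enough to capture artifact signatures, and analyzers
whose behavior can be validated against closed forms and ground truth. This
vignette records the models, the defaults and the design decisions, so a
reader can judge what a passing test suite does — and does not — demonstrate
about real clinical images.

## The digital phantom

The phantom is a water-equivalent disk, 110 mm in diameter, rendered at
256 × 256 px and 0.5 mm/px (a 128 mm field of view) with background intensity
1000 in arbitrary CT-number-like units. Four section kinds mirror the layout
of commercial image-quality phantoms:

* **high contrast** — rods of 3, 9 and 20 mm diameter (+200 over background)
  on a 30 mm pitch circle;
* **low contrast** — the same rods at +20;
* **spatial resolution** — six 10 × 10 mm bar groups at 2, 3, 4, 5, 6 and
  8 lp/cm (one group holds exactly *f* line pairs across 10 mm, so bar and
  space pixels balance), bars at ±100 about background;
* **uniformity and noise** — the bare disk.

Additive zero-mean Gaussian noise (default sigma 15) is the only source of
randomness; `generate_section()` is a pure function of its parameters and
seed, and never perturbs the global RNG. All insert positions and sizes live
in a geometry descriptor carried by the image, which is what
`locate_rois()` uses for automatic ROI placement — the same mechanism a
clinical tool uses when it derives ROI positions from the phantom's known
internal distances.

The generator emulates the *geometry and first-order statistics* of a
cone-beam CT of such a phantom. It does not emulate projection physics,
reconstruction filters, spatially correlated noise, HU calibration or
partial-volume blur (the unblurred bar template is deliberately ideal so its
modulation has an exact closed form). Consequently, a passing suite shows
that the analysis chain is correct and that the classifier recovers
class-consistent signatures above noise — not that the specific artifact
magnitudes equal those of any particular scanner.

## Artifact models

Clinically, these artifact families arise when individual corrections in the
reconstruction chain fail; here each is a closed-form image-domain
perturbation with a magnitude in intensity units (magnitude 0 is the
identity). Defaults were chosen once so that every class except crescent is
separable above the noise floor, and multi-artifact images apply injectors
in the fixed order scatter → beam hardening → rings → crescent:

* **rings** (detector gain errors): alternating-sign offsets (±30) on four
  annuli at radii 10, 18, 26, 34 mm, width 1.5 mm. Pixels outside the
  annuli are untouched.
* **scatter**: a radial dome `a·(1 − r²/R²)` (a = 60) over the disk plus a
  10 % multiplicative contrast reduction toward background. The dome raises
  the centre against the periphery, so the uniformity metric grows strictly
  with the amplitude.
* **beam hardening**: a cupping depression `−a·(1 − r²/R²)` (a = 50) over
  the whole disk, plus dark streaks (−40, 1.5 mm wide) on the segments
  joining high-density rods where such rods exist. The phantom-wide cupping
  is deliberate: only the high-contrast section has dense inserts, yet beam
  hardening must leave a signature in every section.
* **crescent** (residual bowtie-filter motion): a thin lune — the set
  difference of two 18 mm-radius disks offset by 0.5 mm — convolved with a
  2 mm Gaussian point-spread, at nominal amplitude 10. Bowtie shading is
  smooth, so the feathered model is the physical one; it also removes the
  sharp-edge signature that gradient features would otherwise pick up. With
  these defaults the crescent's integrated signal sits below the
  between-image standard error of every feature, which is exactly the
  near-degeneracy with regular images that the classifier study expects.
  The realized peak of a feathered thin lune is below the nominal
  amplitude; the magnitude parameter describes the underlying shading
  before the point-spread.

## Classical metrics

* **CNR** per rod: `|mean(rod) − mean(bg)| / sd(bg)`, rod ROIs shrunk by a
  0.7 margin factor to avoid edge pixels, background ROI a 20 mm disc at the
  phantom centre. Invariant to global offset and positive gain; a zero-variance
  background is a signalled error, not a division by zero.
* **MTF** by the standard-deviation method: for a bar group of frequency
  *f*, the noise-corrected modulation is
  `M'(f) = sqrt(max(sd_group² − sd_noise², 0))` with `sd_noise` estimated
  from a uniform 8 × 8 mm patch of the same section, and
  `MTF(f) = clip((π√2/4) · M'(f) / M0, 0, 1)` with `M0 = 100`, half the
  bar/space peak-to-peak amplitude. For an ideal square-wave group the ratio
  is π√2/4 ≈ 1.11, so the unblurred template clips to exactly 1.0 at every
  frequency — a closed-form anchor the tests assert. MTF50/MTF10 come from
  linear interpolation in frequency between bracketing groups, with no
  extrapolation: a curve that never crosses the level reports `NA` rather
  than a fabricated number (on the ideal template MTF50 is therefore
  undefined, and that column is simply excluded from a section's classifier
  feature pool).
* **Uniformity and noise**: noise is the standard deviation in a 15 mm
  central ROI; uniformity is the worst absolute difference between the four
  peripheral ROI means (38 mm radius, N/E/S/W) and the central mean. Both
  are exactly 0 on a noiseless flat disk.

## The 99-feature texture battery

Every section is also described by a fixed-order texture block computed over
the whole section (the interior of the phantom disk):

* **5 first-order statistics** — mean, SD, entropy (256-bin equal-width
  histogram over the sample min–max, in bits), skewness and excess kurtosis
  (standardized central moments, defined as 0 for a constant sample);
* **76 co-occurrence features** — 19 named scalars per direction for the
  four directions 0°, 45°, 90° and 315° at pixel distance 1. Pixels are
  quantized to 8 gray levels by equal-width binning over the section's
  min–max (hence invariance to any increasing affine rescaling), and each
  matrix is symmetric and normalized, with only pixel pairs fully inside the
  ROI contributing. Descriptions of this battery are ambiguous between 8 gray
  levels and an 8-pixel offset; the nearest-neighbour reading favours
  8 levels at distance 1, which is the default, and both `levels` and
  `distance` remain arguments. The 19-scalar list
  (contrast, correlation, dissimilarity, energy, entropy, homogeneity,
  inverse difference, inverse difference normalized, inverse difference
  moment normalized, the two information measures of correlation, maximum
  probability, autocorrelation, cluster shade, cluster prominence, sum
  average, sum entropy, sum variance, difference entropy) was fixed so that
  it contains every co-occurrence feature the selection study reports while
  reaching exactly 19 per direction;
* **18 scale features** — for scales 1, 2, 4: mean and SD of the
  Gaussian-smoothed intensity, of the central-difference gradient magnitude
  and of the discrete Laplacian (first-order, gradient and second-order
  responses). The ROI is eroded by the kernel support before summarizing, so
  values outside the ROI never leak in; on a linear ramp the interior
  gradient mean equals the slope exactly, at any scale.

The block is exactly 5 + 76 + 18 = 99 values in a documented registry order;
the section's classical metrics (CNR per rod, MTF50/MTF10, or
uniformity/noise) are appended under their reporting names ("CNR 3 mm", …),
giving the feature vector the classifier consumes. With symmetric matrices
315° coincides with the 135° diagonal, which is why those four directions
form the standard complement.

## One-vs-all classification with sequential forward selection

Each (section, class) pair gets an independent binary head: a linear SVM
(C = 1, hinge loss) on z-scored features. Cross-validation is stratified
10-fold with a recorded fold seed; within each fold the standardization
parameters are computed on the training split only — a leak-freedom contract
the tests enforce by comparing against a hand-rolled fold loop on data with
planted outliers. Feature selection is a greedy wrapper: at each step the
candidate whose addition minimizes the CV error joins the model; ties break
toward the lowest registry index; selection stops when no addition strictly
improves the error, when the error reaches 0, or at `max_features`
(default 5). The stopping rule and tie-break are not dictated by the source
method description; they were fixed for determinism.

Multi-label images count as positive for every artifact they carry, so a
rings + beam-hardening image trains (and fires) both heads. At classify
time each head votes independently on its selected features, standardized
with the stored full-data scaler; "regular" is reported when no artifact
head fires. Models serialize to JSON and restore to identical predictions.

The default study is 40 images per class (regular plus the four single
artifacts) per section — 800 images. On it, the test suite verifies the
expected error pattern: beam hardening at CV error 0 in all four sections,
rings at 0 in the low-contrast section, scatter at or below 0.03 in the
uniformity section, and crescent-vs-regular indistinguishable from chance.
For the last check a subtlety matters: an SFS-minimized CV error is
optimistically biased (it is the minimum over ~100 adaptive candidates), so
"chance" for it is well below 0.5. The test therefore builds a
label-permutation null of the *same* selection procedure and requires the
observed crescent error to fall inside it — a selection-aware version of a
binomial chance interval.

## Winston-Lutz analysis

The analyzer finds the radiation-field circle and the ball bearing (BB) on a
portal image by threshold-band centroiding: the unweighted geometric centre
of the pixels inside an intensity band, with the field band defaulting to
2500–2700 and the BB band to 1700–2200, both configurable. One refinement is
needed for unbiased recovery: the BB shadow lies inside the cone field, so
the field-band pixels alone form a disk with an off-centre hole whose
centroid is dragged away from the BB; the field circle is therefore
centroided over the union of the two bands, which restores the full disk,
while the BB uses its own band. An empty band is a signalled error naming
the band, and a series containing an unanalyzable image is reported
indeterminate rather than silently passing.

The synthetic generator renders the field at 2600 and the BB at 1950 into
those default bands (cone 30 mm, BB 10 mm in the detector plane — a 5 mm
bearing and 15 mm cone at roughly ×2 EPID magnification) and returns exact
ground-truth centres. Two numerical facts shape the tests: a discretized
disk mask of radius ≥ 20 px recovers its centre to better than 0.1 px at any
sub-pixel position (smaller BBs can exceed that bound, which set the default
BB size), and when the BB offset is an integer number of pixels the two
masks share their discretization error, so the offset is exact to machine
precision — the 3-4-5 check `(0.6, 0.8) mm → 1.000 mm` is rendered at
0.2 mm/px for precisely that reason. The offset tolerance defaults to 1 mm
(the SBRT profile) with 2 mm available for regular IGRT; a series passes
only if every image passes.

## QA pipeline

Baselines store per-metric reference values with tolerances (relative by
default, 10 %; absolute available per metric — the right choice for
near-zero metrics like uniformity, where a relative band collapses). The
monthly run chains ROI location → metrics → baseline comparison → feature
extraction → artifact classification into a `qa_report` whose JSON form is
timestamp-free and therefore byte-identical across reruns on identical
inputs. The daily couch-shift check takes the applied and recovered shift
vectors as inputs (registration itself is a vendor function and out of
scope), limits applied shifts to 2 cm per axis, and applies the 0 ± 2 mm
(IGRT) or 0 ± 1 mm (SBRT) residual profile per axis.

## Problem sizes and limitations

The test suite and the acceptance script run the full default study
(800 images, 10-fold CV, greedy selection over ~104 candidate features per
section) in a few minutes on one CPU; oracle comparisons use 8 × 8 images
and 40-sample toys where brute force is exact. Known limitations: the
artifact magnitudes are surrogates, not calibrated to any scanner; texture
features are 2D and unweighted by slice context; the MTF method assumes the
bar geometry of the resolution section; DICOM input is not implemented
(16-bit TIFF with JSON sidecars is the interchange format); and the
crescent's near-degeneracy is a property of these defaults, not a law — on a
machine with real bowtie sag a crescent classifier may well be trainable,
and the pipeline supports exactly that by re-running the same study on
images that carry the artifact.
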