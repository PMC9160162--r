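---
title: "Counting and phenotyping endosymbionts in host-cell micrographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting and phenotyping endosymbionts in host-cell micrographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endoquant)
```

## The problem

Obligate bacterial endosymbionts such as *Buchnera aphidicola* live densely
packed inside specialized host cells (bacteriocytes). Because these bacteria
are unculturable and polyploid, genome-copy assays (qPCR) do not measure the
number of bacterial *cells*, and flow cytometry loses the per-host-cell
context. Counting cells directly in confocal micrographs is the alternative,
but a single bacteriocyte image can hold hundreds to thousands of small,
tightly clustered toroidal objects — far beyond what manual counting or
global thresholding can handle.

`endoquant` implements the full tile-and-stitch counting pipeline around a
pluggable per-tile object detector, together with the annotation
conversions, the detection-evaluation procedure, per-cell morphometrics, and
the statistical battery used to analyse developmental series. Every stage is
testable offline against a synthetic scene generator with exact ground
truth.

## Pipeline model

An input micrograph (single DAPI-like channel, PNG, at least 512 px per
side) is processed as:

1. **Tiling.** The image is cropped into 512 px tiles with an 85 px overlap
   between adjacent tiles (stride 427 px). The final window on each axis is
   clamped to end at the image edge; for a 2,048 px image this yields
   exactly 5 × 5 = 25 tiles, for 1,024 px 3 × 3. The overlap exists so that
   every object of typical size (~2 µm ≈ 20 px diameter) lies wholly inside
   at least one tile; the clamping choice is the only geometry under which a
   fixed 85 px overlap and a 5 × 5 grid on 2,048 px are simultaneously
   consistent, and it generalizes to any image at least 512 px per side.
2. **Detection.** Each tile passes through a detector satisfying a fixed
   contract: at most 1,000 detections per tile, every score in [0.01, 1],
   nothing emitted below the 0.5 score threshold. Edge tiles smaller than
   512 px (possible only with non-default tiling) are zero-padded and
   detections cropped back.
3. **Stitching.** Per-tile detections are translated into global image
   coordinates by pure offset arithmetic; nothing is dropped here.
4. **Size filtering.** The median mask area *m* is computed over the whole
   stitched image; detections with area strictly below 0.10 *m* or strictly
   above 5 *m* are removed as false positives. Areas exactly at either bound
   are kept.
5. **Duplicate suppression.** Within the tile-overlap zones, one member of
   any pair of detections with mask IoU strictly above 0.5 is dropped by a
   seeded coin flip. Pairs are visited greedily over candidates sorted by
   mask centroid, which makes chains of three or more mutual duplicates
   resolve deterministically for a fixed seed. Detections wholly outside
   every overlap zone are never touched, matching the motivation of the
   step (double counting can only arise in the overlaps).
6. **Result file.** The retained masks are written as a JSON "result"
   file. Masks are stored as per-row pixel runs, which round-trip the pixel
   sets exactly; polygon outlines would not survive re-rasterization
   bit-for-bit under any fill convention, which is why runs were chosen.

The pipeline is a pure function of (image, detector, configuration, seed);
repeated runs produce byte-identical result files.

### Curation

The production tool pairs detection with an interactive GUI in which a
human removes false positives and adds missed objects. `endoquant` keeps
those semantics but replaces the GUI with a batch *edit file*: a JSON
document listing detection indices to remove and polygon rings to add.
Removals are applied before additions, so indices always refer to the
uncurated result, and an edit is reversible given its inverse. This keeps
curated analyses scriptable and testable.

## Detector

The detector the pipeline was designed around is a Mask R-CNN variant whose
configuration is captured (and validated) by `default_detector_config()`:
ResNet50 backbone blocks 2–5 feeding a feature-pyramid network with 16, 32,
64 and 128 px maps; square anchors of 32, 64, 128 and another 128 px (the
16 and 256 px defaults are dropped as mismatched to the object scale); up
to 1,000 proposals per tile; a 4-layer × 256-channel mask head and a
2-layer × 1,024-unit box head; 40,000 SGD iterations with warmup and cosine
decay; training-set augmentation with brightness and contrast factors in
[0.6, 1.8], isotropic scale in [0.5, 1], and independent horizontal and
vertical flips. Training and trained weights are out of scope here — the
schema documents and validates the configuration, and `augment_sample()`
implements the augmentation operators (contrast pivots on the image mean,
the common convention where none is stated).

For desk-scale work the package ships `baseline_detect()`, a deterministic
classical detector written for the synthetic scenes: difference-of-Gaussians
band-pass smoothing (σ = 3 and 12 px) isolates ring-scale structure and
cancels the large flat nucleus, Otsu thresholding and hole filling produce
solid blobs, and a distance-transform watershed splits touching objects.
Each segment is scored by a ring-likeness statistic — the normalized
contrast between the segment's outer annulus and its centre, multiplied by
its circularity (with the 4-connected edge count corrected by π/4 to
approximate a true perimeter) — mapped affinely into [0.01, 1]. The
parameters are tuned to the generator's default geometry (~1 µm radius at
10 px/µm) and the detector is a stand-in for exercising the pipeline, not a
substitute for a trained network on real data. Its one known failure mode:
two objects in sub-pixel contact produce a fused blob with no distance-map
saddle and can merge into one detection (observed once in 360 objects
across twelve dense 30-object scenes; never at 10 objects per tile).

## Evaluation

Detection quality follows the standard procedure exactly: a prediction is a
true positive iff its IoU with a still-unmatched annotated object is
strictly greater than 0.5 (greedy matching in descending score order, each
ground truth consumable once); recall = TP / number of annotated objects;
precision = TP / number of predictions; F1 is their harmonic mean. For the
precision–recall curve, scores are sorted ascending and split into 100
equal-count bins (counts differ by at most one; with fewer than 100
distinct scores, one threshold per distinct score); the bin maxima are the
thresholds, and at each threshold the prediction subset with score ≥ t is
evaluated — the inclusive convention keeps the top bin non-empty. Average
precision is the trapezoidal area under the (recall, precision) points
anchored at the extrapolated point (recall 0, precision 1) and *not*
extended beyond the maximum observed recall; no 11-point or all-point
interpolation is applied. The F1-maximizing threshold is reported with ties
broken toward the smaller threshold.

## Morphometrics

With the whole-cell and nuclear areas measured externally (e.g. in FIJI)
and supplied in µm², `compute_cell_metrics()` evaluates, per cell:

1. cytoplasm area (µm²) = whole-cell area − nuclear area;
2. density (µm⁻²) = object count / cytoplasm area;
3. per-object areas converted from px² to µm² by dividing by the squared
   pixels-per-micron ratio — the conversion text is ambiguous about the
   ratio's orientation, so the dimensionally correct reading is the default
   and the orientation is exposed as an argument;
4. per-object "diameter" (µm) = √(area / π) — implemented verbatim; note
   that this expression is geometrically the *radius* of the equal-area
   circle, and the name is kept only for continuity with the established
   metric;
5. occupied cytoplasm fraction = (union area of all object masks) /
   cytoplasm area — multi-way overlaps are counted once via the pixel
   union, and the value is reported both as a fraction and ×100.

Outliers are trimmed by absolute z-score > 3 (strict), computed in a single
pass from the sample mean and n−1 standard deviation of the full input:
object-level areas within each timepoint, cell-level metrics across all
cells. Re-running the trim on the kept set could remove more points; the
pipeline deliberately runs exactly one pass.

## Statistics

`compare_groups()` routes on homoscedasticity: the classic mean-centered
Levene test at α = 0.05 (the routing threshold is a package decision; the
procedure's description names only "Levene's test") sends homoscedastic
data to one-way ANOVA with Tukey HSD grouping and heteroscedastic data to
Kruskal–Wallis with two-sided normal-approximation Dunn comparisons under
Benjamini–Hochberg correction. Compact letters are produced by
insert-and-absorb over the adjusted pairwise matrix, so groups share a
letter iff no significant pairwise difference separates them. Trends
against age use Spearman rank correlation; variability across the adult
timepoints is tested by replacing each value with its absolute deviation
from its own group mean and applying the non-parametric branch; regression
slopes over adulthood are reported with the 95% interval slope ± 1.96 ×
SE(slope) — the interval's half-width is read as 1.96 standard errors of
the slope estimate, the only reading that yields a meaningful confidence
interval.

Calibration is checked by simulation in the test suite: the full
variance-routed route holds a ~5% type-I error under a Gaussian null
(4 groups × 20 values, 1,000 replicates), and the slope interval covers a
true slope at ~95% over 1,000 Gaussian-noise regressions (n = 200).

## Synthetic scenes

`generate_scene()` renders what the detection stage actually consumes: a
dark background, an elliptical cell, a bright elliptical nucleus, and *n*
toroidal objects — bright annulus (default outer half of the radius), dim
central hole — plus Gaussian noise, with radii drawn from a truncated
normal (default 1 ± 0.15 µm at 10 px/µm, matching the scale at which a
32 px smallest anchor is sensible). Placement is seeded rejection sampling:
objects lie wholly inside the cell ellipse, clear of the nucleus, and honor
a maximum pairwise disk-overlap fraction (0 = disjoint). Ground-truth masks
are the *filled disks*, since annotators outline whole cells; the torus is
purely a rendering property, and every rendered object has a central
intensity minimum. All randomness flows from one seed through deterministic
sub-streams, so scenes are bit-reproducible.

What the generator does *not* emulate: optical point-spread blurring,
depth-dependent intensity falloff, vacuoles, debris, ruptured cells, and
the irregular shapes of real bacteria. Passing tests on synthetic scenes
therefore demonstrate the correctness of the pipeline machinery —
geometry, conservation, evaluation identities, statistical calibration —
not the real-data accuracy of any particular detector.

`degrade_truth()` corrupts ground truth into imperfect "predictions" with
known error structure (drop a fraction, jitter survivors, add clutter that
provably cannot match truth, scores in controlled bands), which makes
evaluation identities exact: recall = 1 − drop fraction and precision =
TP/(TP + clutter) at the lowest threshold. `generate_cohort()` builds
multi-timepoint cohorts with Poisson-distributed counts around
per-timepoint expectations (count and radius multipliers), by default
skipping intensity rendering and carrying analytic disk areas, which is all
the morphometrics and statistics stages need and keeps hundred-replicate
power simulations cheap.

## Problem sizes used in the checks

The shipped tests and the acceptance script use: 512–1,024 px scenes with
10–100 objects; 100-instance property sweeps for the geometry and AP
oracles; 1,000 replicates for the type-I and coverage calibrations; and 100
cohort replicates (2 timepoints × 16 cells, 60 objects expected per cell,
1.5× count step) for parameter recovery — sizes chosen so the whole battery
completes in minutes on one CPU while keeping Monte-Carlo error well inside
the asserted bands.

## Known limitations

- The baseline detector is tuned to the generator's geometry; on real
  micrographs a trained neural detector behind the same `detect_tile()`
  contract is required.
- Dense packing beyond the overlap cap (objects in sub-pixel contact) can
  merge under the classical watershed split.
- Multi-class labels are carried through the data model (masks have a
  label field), but no multi-channel renderer or multi-class evaluation is
  provided.
- Cell and nucleus segmentation is out of scope; those areas are inputs.
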