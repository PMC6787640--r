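---
title: "Methods: semi-automated AO urinalysis image analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semi-automated AO urinalysis image analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aosediment)
```

## The measurement problem

A urine specimen stained with acridine orange (AO) is imaged as one or
more colour fluorescence fields of view (FOVs). The sediment relevant
to diagnosing a urinary tract infection — squamous/transitional
epithelial cells, leukocytes (predominantly granulocytes) and bacteria
— all take up AO and fluoresce against a dark background, so a single
global threshold separates objects from background. The task is to
detect each object, measure two features (calibrated area and the
red-to-green intensity ratio), assign one of four classes (epithelial,
leukocyte, bacteria, cellular debris), and report per-specimen counts
in the clinical range vocabulary used by manual microscopy.

Two camera passes per FOV exist in the acquisition model this package
assumes: a *high-exposure* pass in which dim bacteria are easier to see
but bright cells clip, and a *low-exposure* pass in which nothing
clips. After linear contrast enhancement bacteria are resolvable in the
low-exposure pass, so only low-exposure frames are analysed; the
high-exposure frames are accepted, flagged and skipped (an
`include_high_exposure` switch overrides this for exploration).

## Pipeline and assumptions

1. **Contrast enhancement** (`enhance_contrast`): per channel, a linear
   stretch mapping the 1st percentile to 0 and the 99.9th percentile to
   the bit-depth maximum, clipped outside. The stretch is applied to a
   copy; every quantitative measurement (saturation testing, RG ratio,
   focus score) uses the original pixels, because a linear map with
   clipping can both fabricate and hide ceiling values and distorts
   channel ratios. A constant channel is returned unchanged.
2. **Binarization** (`binarize`): global Otsu threshold on the green
   channel of the enhanced frame. Green is the natural detection
   channel: AO emission is green-dominated for all three cell classes.
   The contract assumes bright objects on a dark background; a constant
   image yields an all-background mask rather than an error.
3. **Labelling** (`label_objects`): 8-connected components via a
   two-pass union-find (compiled). 8-connectivity is chosen so that
   bacterial rods linked end-to-end — including diagonally — remain
   one object. Components smaller than `min_object_px` (default 4 px)
   are dropped as shot noise but tallied, so the accounting below stays
   exact. Object identifiers are deterministic (components numbered by
   the raster position of their first pixel), which makes whole-run
   outputs byte-reproducible.
4. **Exclusion flags** (`flag_exclusions`): objects touching any image
   border misrepresent their area; objects containing a pixel at or
   above the saturation level (default: the bit-depth ceiling)
   misrepresent their fluorescence. Both are flagged, not deleted —
   exclusion happens at enumeration so the object table keeps a full
   audit trail.
5. **Features** (`compute_area`, `compute_rg_ratio`,
   `compute_focus_score`): area is `n_px · s²` (exactly linear in pixel
   count, quadratic in the calibration `s`); the RG ratio is the ratio
   of channel *means* over the mask (robust to mask size; invariant
   under common gain; undefined — `NA` — when the mask has no green
   signal, in which case the object is routed to debris); the focus
   score is the mean central-difference gradient magnitude of the green
   channel over the object's boundary pixels, divided by the object's
   mean green intensity. Normalising by brightness makes the score an
   edge-sharpness measure: debris and bacteria overlap in both RG
   ratio and area, and only edge quality separates them.
6. **Classification** (`classify_objects`): in precedence order,
   (i) edge/saturation ⇒ `excluded`; (ii) undefined RG ratio, or focus
   score below `debris_focus_threshold` while the area class would be
   bacteria or leukocyte ⇒ `debris` (large in-focus epithelial cells
   are never debris); (iii) otherwise the area rule: `> 500 µm²`
   epithelial, `< 30 µm²` bacteria, leukocyte in between. Both
   thresholds are strict, so the leukocyte interval is closed —
   exactly 30 or 500 µm² is a leukocyte. The RG ratio is carried in
   every output table but never used in the decision: in this assay
   area separates the classes while the RG ratio shows no classifiable
   pattern.
7. **Enumeration** (`enumerate_specimen`): totals and per-FOV means per
   cell class, the clinical range category for each total, and the
   exclusion tally by reason. The clinical bins are made disjoint —
   `Trace (0–2)`, `Few (3–10)`, `Moderate (11–25)`, `Many (>25)` — by
   assigning a count of 10 to `Few`; clinical practice writes
   overlapping bin edges (10–25 vs 3–10), but a report must map each
   integer to exactly one bin. Both totals and per-FOV means are
   reported because clinical counts are averaged over a fixed number
   of FOVs while an imaging system naturally reports absolute counts.
   Conservation is enforced: class counts + exclusions (edge,
   saturation, sub-floor, debris) = detected components.

## Tunable parameters

| Parameter | Unit | Default | Rationale |
|---|---|---|---|
| `pixel_size_um` | µm/px | *(required)* | FOV area is known (≈0.15 mm²) but sensor geometry is instrument-specific; never guessed. |
| `epithelial_min_area_um2` | µm² | 500 | Published class boundary. |
| `bacteria_max_area_um2` | µm² | 30 | Published class boundary. |
| `saturation_level` | intensity | bit-depth max | The ceiling defines "saturated" unless the camera clips earlier. |
| `min_object_px` | px | 4 | Suppresses single-pixel shot noise while keeping 1–3 µm² bacteria at typical calibrations. |
| `debris_focus_threshold` | — | 0.38 | Calibrated on the phantom generator (below). |

### Calibration of the focus threshold

The debris cutoff is the one tunable without a published value. It was
calibrated once against the phantom generator at its defaults: over
seeded renders, in-focus bacteria score ≥ ≈0.46 and Gaussian-blurred
debris ≤ ≈0.31, so the default 0.38 sits mid-gap and rejects
generator-default debris while retaining sharp bacteria at well over
95% each (in practice 100% in every seeded run). The value is stored
in `calibration_config()` and should be recalibrated for optics whose
point-spread function differs materially from the generator's blur
model.

## The phantom generator

`phantom_spec()` / `render_phantom()` simulate one AO field of view
with complete ground truth. The default scene matches the study scale:
a 640 × 640 px frame at 0.6 µm/px (0.147 mm², close to the 0.15 mm²
FOV of the reference acquisition) containing 20 epithelial cells, 50
leukocytes, 200 bacteria and 30 debris blobs. Geometry per class:

* **epithelial** — ellipse (aspect 1.2–2) with a brighter compact
  nucleus; lognormal area, median 800 µm²;
* **leukocyte** — disk with 2–4 bright nuclear lobes; the red channel
  is multiplied by `leukocyte_red_shift` (default 1.8) to model the AO
  red shift in acidic granules — cosmetic only, since classification
  ignores the RG ratio; median area 90 µm²;
* **bacteria** — rotated rods, median area 4 µm², rendered ≥ 2 px wide:
  a 1 px line has zero central-difference gradient, so thinner rods
  would be invisible to the focus score purely as a sampling artifact;
* **debris** — disks blurred with a Gaussian of
  `debris_blur_sigma_px` (default 2), matching bacteria in RG ratio
  and area but not in edge sharpness.

Area draws are clamped a safe margin away from the 30/500 µm² class
boundaries so that a phantom's true class always agrees with its true
area; this is the "well-separated" study condition under which exact
count recovery is a meaningful target. Additive Gaussian sensor noise
(default sd 2 of 255) is applied last; optional fractions of objects
are placed touching the border (`edge_fraction`) or rendered with
ceiling-clipped cores (`saturation_fraction`), and the truth table
records, for every object, the class, rasterised area, centroid, edge
contact, actual saturation in the rendered frame, and blur width.
Placement keeps a guard gap between objects; if a scene cannot be
packed within the retry budget, a placement error reports how many
objects fit.

Class intensities (bacteria ≈100, cell bodies 120–135, nuclei/lobes
≈200 on the 8-bit scale) were fixed at design time so that one global
Otsu threshold on the enhanced green channel retains all four classes.
With genuinely dim bacteria and this object mix, Otsu provably prefers
splitting bright cells from everything else and drops the bacteria —
the regime the two-exposure acquisition exists to avoid. The simulated
high-exposure frame is therefore the low-exposure scene scaled by
`high_exposure_gain` (default 2.5, clipping the bright cells); it is
rendered for completeness and never analysed by default. One
consequence is that simulated bacteria end near (not far below) the
ceiling in the high frame; since no pipeline stage consumes that frame,
the compromise is cosmetic.

**What the phantoms do not emulate:** optical point-spread functions
(blur is a plain Gaussian), Poisson photon statistics (noise is
additive Gaussian), illumination-field inhomogeneity, stage-motion
blur, overlapping or touching cells (the pipeline counts one object
per connected component by design), erythrocytes, casts, crystals and
yeast. Passing the phantom suite therefore demonstrates the
correctness of the segmentation/feature/classification logic under the
stated model, not clinical performance on patient images.

## Interobserver agreement

Manual classification tables (object × rater × label) are scored with
a pairwise convention: for class *c*, over all rater pairs and objects
for which at least one rater of the pair assigned *c*, the statistic is
the percentage where both did. The published per-class percentages do
not state their formula, so this convention is declared rather than
assumed to match; the implementation is verified against an exhaustive
pair-enumeration oracle. Classes never assigned by any rater are
reported as missing (`NA`) rather than 0 or 100.

## Numerical choices and degenerate inputs

* Otsu's threshold is computed on the full histogram at native bit
  depth; a constant image short-circuits to an empty mask.
* Quantile type 7 (R's default) anchors the percentile stretch; the
  stretch is the identity when the anchors coincide.
* Gradient at image borders uses replicated edge pixels; objects for
  which this matters are edge-touching and hence excluded anyway.
* Boundary pixels are mask pixels with a 4-neighbour outside the mask
  (or outside the image), listed in deterministic raster order.
* `NA` feature values never propagate silently: an undefined RG ratio
  forces the debris class, and classification refuses to run on
  objects whose exclusion flags were never set.
* Test and acceptance problem sizes: study-scale phantoms (300 objects,
  640 × 640 px) for the recovery and exclusion checks, 320–420 px
  scenes for property sweeps, 10 seeds × 3 noise levels for the
  degradation monotonicity check, and the exhaustive 65,536-mask 4 × 4
  comparison plus 100 random 32 × 32 masks for the labeller oracle.

## Known limitations

* The area rule is calibration-critical: a miscalibrated
  `pixel_size_um` shifts every class boundary quadratically.
* Touching cells are counted as one object (no watershed splitting);
  dense specimens will undercount.
* Inverted-contrast images (dark objects on bright background) are out
  of contract for `binarize`.
* The focus threshold default is generator-calibrated; real defocus
  depends on the optical train and should be recalibrated per
  instrument.
* Counts are reported per analysed FOV set; no attempt is made to
  normalise to the 9-FOV/0.134 mm² convention of manual microscopy
  beyond reporting per-FOV means alongside totals.
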