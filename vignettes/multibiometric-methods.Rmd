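---
title: "Hand geometry and dorsal vein minutiae: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hand geometry and dorsal vein minutiae: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(handvein)
```

## The verification problem

`handvein` verifies an identity claim from a single 640 × 480, 8-bit
grayscale image of the back of a hand held over a dark matte surface, as
produced by a near-infrared (≈ 850 nm) acquisition rig. Deoxidized
hemoglobin absorbs NIR strongly, so veins image darker than the
surrounding tissue while the hand as a whole is much brighter than the
background. Two independent biometric modalities are extracted from the
same frame:

* **hand geometry** — 62 contour measurements: five finger lengths, ten
  width stations per finger, the three adjacent fingertip gaps (the
  thumb–index gap is excluded as too variable), the three adjacent
  finger-valley gaps, and the palm width;
* **dorsal vein minutiae** — branch and end points of the vein skeleton
  inside a region of interest (ROI) on the dorsum.

Each probe is scored against a stored per-subject template with distance
metrics, scores are min–max normalized over the comparison batch, the two
modality scores are fused by their arithmetic mean, and the claim is
accepted when the fused score is at or below a threshold (default 0.5).
Performance is summarized by FMR/FNMR curves over the threshold sweep and
their crossing, the equal error rate (EER).

## Hand-geometry pipeline

1. **Preprocessing** — a 3 × 3 averaging core smooths sensor noise.
2. **Segmentation** — a global threshold at `mean(intensity) − hand_tg`.
   On a dark-background scene the global mean sits just above the
   background level, so the constant must be *negative*; the default
   `hand_tg = −60` places the threshold near the blur's half-intensity
   level, which keeps the mask edge on the true object boundary (a
   threshold below that level grows the silhouette by about a pixel per
   side and biases every width measurement).
3. **Pose normalization** — the principal axis of the silhouette is
   rotated to the vertical by the smallest rotation; the protocol
   presents the hand fingers-up within ±10°, so this never flips it.
4. **Landmarks** — the boundary is traced (Moore tracing of the largest
   8-connected component), its convex hull is computed, and convexity
   defects deeper than `min_depth` (default 20 px) give the four finger
   valleys. A defect under a tilted hull chord lands on a *corner* of an
   inter-finger gap, so each valley is re-centered on its gap floor (the
   midpoint of the contour points within 3 px of the locally deepest
   row). Fingertips are hull-vertex clusters above the palm center; the
   tip within a cluster maximizes contour curvature (the angle between
   the two direction vectors `curvature_k = 15` contour points away).
   Because a rounded cap has constant curvature, near-ties are broken
   toward the cap apex. Finger bases follow the neighboring-valley
   construction: the midpoint of the two adjacent valleys for the middle
   and ring fingers, and the adjacent valley reflected across the finger
   axis for thumb, index and pinky.
5. **Measurement** — lengths are tip-to-base distances; widths are the
   silhouette extent along the perpendicular at 5 %, 15 %, …, 95 % of
   the tip→base axis, averaged over three parallel scan lines to smooth
   raster stair-stepping; the palm width is the extent through the palm
   center perpendicular to the middle-finger axis.

### Template and geometry scores

Enrollment uses `n_enroll = 2` captures. The template stores, per
feature, the mean and the RMS deviation from that mean, floored at
`sigma_floor = 0.5` px so that coinciding enrollment captures cannot
produce a degenerate gate. Two metrics compare a probe `x` against the
template:

* Euclidean distance `sqrt(sum((x_i − mean_i)^2))`;
* a generalized Hamming distance: the *count* of features whose deviation
  strictly exceeds the template's RMS spread, `#{i : |x_i − mean_i| >
  sigma_i}` — a 0–62 integer that ignores how far a feature is off, only
  whether it is off.

## Vein pipeline

The ROI starts at the finger-joint level: its top edge spans valley 2 to
valley 4, its width is that distance, and its height is 1.4 × the width,
extending toward the wrist; the crop is resampled so the vein axis is
vertical. Segmentation is: 11-px median (suppresses skin texture but
keeps band-like structures), histogram equalization, local mean
thresholding of the *inverted* ROI so the dark veins become object
(window `vein_surrounding = 21`, offset `vein_tg = −3`, i.e. a vein must
exceed its local mean by 3 counts — with a positive offset every pixel of
a flat region would trivially pass), a 3-px median, a closing
(radius 1), and filling of enclosed holes up to 50 px (an adaptive
threshold hollows out any object wider than its window, which would
otherwise split skeleton junctions).

The mask is thinned with the Zhang–Suen algorithm — the two parallel
sub-passes iterated to a fixed point — followed by two topology repairs
the textbook parallel scheme needs: a compact object that shrinks to a
2 × 2 square is deleted entirely in one sweep (its component would
vanish), so any input component without a skeleton survivor gets one
representative pixel back; and at diagonal crossings the transition
count overcounts arms that are already linked within the neighborhood
ring, stranding 2 × 2 blocks, so a block pixel is removed whenever its
object neighbors remain one 8-connected set without it. With the
repairs, thinning preserves the 8-connected component count and leaves
no 2 × 2 block — the invariants the rest of the pipeline (and the
crossing-number classification) relies on. Thinning is run on an
edge-replicated padding of the mask so that veins cut off by the ROI
frame keep their skeleton all the way to the edge instead of retracting
by half a band width. Spur pruning removes isolated pixels and walks
from every line ending (connection number 1) to the nearest junction,
deleting paths shorter than `max_spur = 25` px; endpoints in the
top/bottom border band are true vein exits and are protected (veins run
longitudinally through a vertical ROI, so side-pointing spur ends are
noise artifacts). Minutiae are then: a **branching** at every pixel with
crossing number ≥ 3 (adjacent junction pixels within 3 px merge to their
centroid), and an **ending** at every connection-1 pixel within
`border_band = 3` px of the top edge. The crossing number is half the
sum of absolute differences around the ordered 8-neighborhood cycle;
its 0–4 range classifies isolated/end/interior/branch pixels. The
stricter reading "crossing number = 4 only" is available as
`branch_min_cn = 4`, but on 1-px skeletons it would leave branchings
nearly extinct, so ≥ 3 is the default.

### Vein scores

Two point-set distances compare the probe's minutiae `A` against the
reference set `B` stored at enrollment:

* the non-oriented Hausdorff distance
  `H(A,B) = max(h(A,B), h(B,A))`, `h(A,B) = max_{a∈A} min_{b∈B} ‖a−b‖`
  — sensitive to a single outlying point by construction;
* the modified Hausdorff distance, which replaces the inner max with the
  *average* nearest-neighbor distance and symmetrizes with a max —
  a single spurious minutia then shifts the score by at most its
  distance divided by the set size.

Minutia kind (branching vs ending) does not restrict the nearest-neighbor
search by default. The sets are **not** centroid-aligned before
matching: the ROI is anchored at the finger valleys, which already
registers translation between captures; centroid alignment would
additionally cancel the lateral layout of a subject's vein pattern —
genuine information. On the development cohort, disabling alignment
roughly halved the vein-MHV EER. Alignment remains available
(`align_minutiae = TRUE`) for acquisition setups without a stable
landmark frame.

## Normalization, fusion, decision

Each metric's raw scores are min–max normalized over the comparison
batch — all genuine plus impostor comparisons in batch evaluation, or
the probe-versus-all-templates scores in single-probe verification. The
fused score is the arithmetic mean of the normalized geometry-Hamming
and vein-MHV scores, and the claim is accepted iff `fused ≤ 0.5` (all
scores are dissimilarities; a score exactly at the threshold accepts).
FMR/FNMR are swept on a 0–1 grid in steps of 0.005, with linear
interpolation at the crossing for the EER; if the curves touch over an
interval the midpoint threshold is reported.

## The synthetic generator

No public dataset accompanies the acquisition protocol this package
models, so all quantitative statements are made on a seeded synthetic
cohort with full ground truth. A subject is a parameter set drawn from
cohort distributions (independent normals truncated at ±3 spreads):
finger lengths (means 95/135/155/145/110 px, thumb→pinky), base widths
(28/25/25/24/20 px), palm width (175 px) and height (150 px), all sized
for the 640 × 480 frame; plus a rooted planar vein tree with 2–4
branchings grown inside the subject's ROI. A capture applies a small
multiplicative intra-subject jitter (`jitter_scale = 0.02`; the
acquisition protocol does not pin this value, so it was chosen once as a
realistic repeat-positioning variability well below inter-subject
anatomical spread), an in-plane rotation of ±10°, a translation of
±15 px, one 3 × 3 averaging pass and additive Gaussian noise
(sd 4 counts), then rasterizes: background 15, hand 180, veins 20–40
counts darker than tissue.

Deliberate simplifications, and what they imply:

* the palm is a superellipse (exponent 4) and the fingers are vertical
  capsules attached along a knuckle arch; there is no perspective, no
  skin texture, wrinkles or hair, and no finger spread variation. The
  flat palm top keeps the four valleys at nearly equal heights, as on a
  real dorsum, and the arch keeps every fingertip a convex-hull vertex —
  subjects are drawn conditionally on a ≥ 6 px hull-protrusion margin
  per tip, because a hull-based extractor (this one or any other) is
  undefined for hands whose fingertip falls inside the hull;
* vein bands are 6–8 px wide. A band narrower than half the 11-px
  median window cannot survive that filter — a band covering less than
  half the window medians away — so the acquisition model assumes veins
  at least ~6 px wide at this resolution, and a narrow ROI additionally
  caps band width so adjacent exits keep a resolvable gap;
* branches fan out toward pre-assigned exit corridors through the ROI
  top edge and keep ≥ ~13 px lateral separation, since bands closer
  than band-width + half the median window fuse into one structure;
* passing tests on this cohort demonstrates correctness of the pipeline
  mechanics and the claimed statistical behavior *under the stated
  acquisition model*; it does not certify performance on real NIR
  imagery, where contrast, perfusion and pose variability are harsher.

### Ground truth

`render_capture()` returns, alongside the frame: the exact silhouette;
the 62 features a perfect extractor would measure, computed analytically
from the capsule/superellipse geometry with the same landmark
definitions the pipeline uses; and the *observable* vein minutiae. The
geometric centerline node of a bifurcation is unobservable in principle:
for bands of halfwidth `h` meeting at opening angle `θ`, any band-image
pipeline sees the junction displaced by about `h / sin(θ/2)` (plus the
median's wedge fill) along the bisector, which exceeds a 3-px match
radius for any realistic width. The ground truth therefore rasterizes
the exact band union the renderer draws, applies the same binary-domain
cleanup the segmentation stage performs, thins it, and snaps every tree
node to its skeleton landmark — dropping nodes whose landmark fused with
a neighbor, since no extractor could report them. Pixel intensities are
never consulted, so the ground truth stays geometry-derived. Node
*counts* still come from the generative tree.

## Numerical choices and degenerate inputs

* Border policy is edge replication for every windowed filter, avoiding
  spurious dark frames that would fool the mean-based thresholds.
* The averaging filter rounds to nearest with ties away from zero (ties
  cannot actually occur for odd cores on integer images).
* Width/palm measurements march in 0.25-px steps along the scan line;
  features are quantized by the integer pixel grid, so recovery
  tolerances carry a 1.5-px absolute floor below which relative errors
  are not meaningful (2 % of a 40-px fingertip gap is under a pixel).
* `measure_hand()` raises a measurement error if a finger axis leaves
  the silhouette; landmark detection raises a detection error when
  valleys or fingertip clusters are missing (e.g. a fingerless disk);
  empty masks raise a segmentation error; single-capture enrollment and
  identical-score normalization batches refuse with enrollment and
  degenerate-batch errors rather than producing scores.
* Min–max normalization requires at least two distinct scores; the EER
  of an everywhere-identical score batch is reported as 0.5 (the
  FMR/FNMR curves sum to one at every threshold).

## Evaluation protocol and sizes

The default experiment mirrors the study shape scaled to desk size:
20 subjects × 7 captures (the acquisition study used 40 × 7 = 280
images), the first 2 captures per subject enrolled, every remaining
capture scored against every template (full cross-comparison; 100
probes × ~20 templates ≈ 1800–1900 comparisons, of which ~90 are
genuine). Five systems are swept: geometry under Hamming and Euclidean,
veins under Hausdorff and modified Hausdorff, and the fused system
(Hamming + MHV). On this cohort the fused EER is comfortably below both
of its constituents, reproducing the qualitative finding that metric
consolidation improves precision; the Euclidean geometry metric happens
to be very strong on synthetic anatomy (its 62 independent dimensions
separate cleanly without skin-texture noise), which is a property of the
generator, not a claim about real imagery. The exact EER percentages of
the original study (5 % fused, 11 % bloodstream) were measured on a
private dataset and are treated as directional only.

Sizes were chosen to keep the full experiment in the low minutes on one
CPU: rendering a capture takes ~0.4 s and the two extraction pipelines
~0.8 s per frame.

## Known limitations

* The generator's vein trees are planar, non-crossing and share an exit
  topology family; real dorsal networks cross, vary in depth and fade.
* The hand model has no perspective foreshortening; only in-plane pose
  is exercised, matching the fixed-rig acquisition assumption.
* The fingertip curvature rule is nearly degenerate on circular caps;
  the apex tie-break makes it deterministic, but on real fingertips
  with flatter caps the `curvature_k` window may need retuning.
* Hamming's gate uses per-feature RMS spreads from only two enrollment
  captures; with more enrollment captures the spreads stabilize and the
  gate sharpens.
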