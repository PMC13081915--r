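---
title: "Methods: decoupled detection and classification of RBC morphology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decoupled detection and classification of RBC morphology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbcscope)
```

## The problem and the design of the framework

Full-scope microscopy fields of sickle-cell blood contain hundreds of
densely packed red blood cells spanning five morphological phenotypes:
discocytes/ovalocytes (DO), echinocytes (E), elongated/sickle cells
(ES), granular cells (G) and reticulocytes (R). Joint
detection–classification architectures localize these cells well but
struggle with fine-grained phenotype assignment, above all for minority
classes. The framework implemented here therefore *decouples* the two
tasks: a detector proposes boxes on the full frame; each box is
cropped, standardized, and classified by a specialized per-cell
classifier ensemble; the predicted labels are then annotated back onto
the frame.

The pipeline stages, in order, with their assumptions:

1. **Detection** (`oracle_detector()` or any function meeting the
   detector contract). Boxes are axis-aligned pixel rectangles under a
   0-based, top-left-origin, half-open convention, so a box's area is
   exactly `w * h` and IoU is unambiguous. Detections below the
   confidence threshold (default 0.25) are discarded.
2. **Crop and standardize** (`crop_and_standardize()`). Each box is
   cropped, padded to a square with the median intensity of the crop
   window's border (the local background), and resized to a fixed
   side (default 224 px). Padding rather than anisotropic resizing
   preserves elongation, the single most discriminative cue for ES
   cells. The pad amounts, origin and scale are recorded so any patch
   coordinate maps back to the frame (`patch_to_frame()`, exact to
   under half a pixel).
3. **Train-time geometric augmentation** (`geometric_augment()`).
   Horizontal/vertical flips (p = 0.5 each), rotation within ±12°,
   translation up to 5% of the side, isotropic scale in [0.95, 1.05].
   No photometric transform is ever applied, so intensity statistics
   carry morphology information only; validation data stays
   unaugmented.
4. **Fold-ensemble classification.** Classifiers are trained under a
   stratified 5-fold split (`stratified_folds()`); stratification is a
   deliberate choice beyond plain k-fold because classes with only a
   couple of hundred samples risk empty validation strata otherwise.
   At inference each fold model contributes its maximum softmax
   confidence to the score of its argmax class; the largest
   accumulated score wins (`ensemble_vote()`). Exact ties break to the
   lowest category index and are flagged. The literal
   max-confidence accumulation rule is the default; full-vector
   averaging is available as `mode = "mean"` for comparison.
5. **Back-annotation.** Predictions become annotations with
   `source = "predicted"` on a copy of the record, exportable to COCO
   JSON and YOLO-style overlay text.

## Imbalance mitigation

Loss level, for `K` classes with counts `n_i`, `N = Σ n_i`:

* inverse frequency `w_i = N / (K n_i)` (satisfies `Σ n_i w_i = N`
  exactly; equal counts give unit weights);
* square-root inverse `w_i = sqrt(N / (K n_i))` — a milder
  re-weighting;
* class-balanced effective number `w_i = 1 / E_i`,
  `E_i = (1 − β^{n_i}) / (1 − β)`, β = 0.9999 by default;
* focal loss `−α_t (1 − p_t)^γ log p_t`, α_t = 0.25, γ = 2 — strictly
  decreasing in `p_t`, reducing to cross-entropy at γ = 0, α_t = 1.

Data level:

* **Oversampling** (`oversample_rare()`): every image holding at least
  one rare-class instance is duplicated to appear
  `k = max(1, round(N_maj r / N_rare))` times, `r` = 0.5 by default.
  The rounding mode (half-up, floored at 1) is a package decision —
  the formula alone does not fix it — chosen as the least surprising
  convention producing a usable positive integer. `N_maj` is read
  literally as the instance count of the single most frequent
  category, computed from the bundle at hand.
* **Copy–paste** (`copy_paste_augment()`): rare patches are extracted
  with a 5 px margin; paste centres are drawn uniformly inside the
  circular imaging region of radius 0.45·min(W, H) — "image size" is
  ambiguous for a non-square frame, and min(W, H) is the only reading
  that keeps the circle inside a 1920×1080 frame; candidates with
  IoU ≥ 0.3 against any existing or earlier-pasted box are rejected,
  up to 50 attempts per paste before skipping with a log entry.
  Blending uses an elliptical mask inscribed in the patch rectangle,
  smoothed by a Gaussian of sd 3 px (the sd is a package default —
  unspecified upstream — giving a visually soft edge a few pixels wide
  at typical cell scales; it is configurable). Per image, 1–3 patches
  are drawn with replacement from the rare pool unless a count is
  fixed; both the count rule and whether paste budgets should be
  class-conditional were left open, so both are configuration.
* **Rare-class cropping** (`rare_crop()`): per rare instance, `k = 2`
  crops of 640×640 centred at the instance centre plus offsets
  `Uniform(−s/4, s/4)`. Windows are clamped inside the frame rather
  than padded, preserving the fixed crop size without inventing
  content. Annotations intersecting a window are retained iff at least
  50% of their box area is visible (a package decision; it avoids
  training targets that are mostly outside the crop), translated and
  clipped. Originals are always retained.

The **rare set** defaults to {E, ES, G, R} for the data-level
operators but is configurable everywhere, because analyses of minority
performance sometimes restrict attention to {E, G, R}; the package
treats the choice as data, not as a constant.

## Evaluation protocol

Matching is greedy one-to-one in descending confidence order — the
COCO convention; the protocol's matching algorithm is otherwise
unspecified, and the test suite keeps an exhaustive maximum-matching
implementation as an oracle to bound how far greedy can fall from
optimal on small instances (it never exceeds it, and on random
micro-instances it is almost always equal). Ties on IoU break toward
the lower ground-truth id. In class-aware mode a detection can only
match its own category; the matching stays strictly one-to-one across
classes. Detection P/R/F1 come from the matched counts; zero
denominators yield 0 with an explicit degenerate flag instead of an
error, because empty classes occur routinely in small synthetic runs.
Classification metrics are one-vs-rest per class with accuracy, macro
averages over all K categories, and support-weighted averages whose
weights are the true-label counts of the evaluated sample — with that
convention support-weighted recall equals accuracy on single-label
data, an identity the tests assert on random inputs. AP uses the
101-point COCO interpolation; mAP@50:95 averages IoU thresholds 0.50
to 0.95 in steps of 0.05, and categories absent from the ground truth
are excluded from the means with a note.

## Training-schedule state machines

Early stopping and reduce-LR-on-plateau are implemented as pure step
functions over explicit state so traces can be replayed and asserted
step for step. Early stopping raises its flag after `patience = 7`
consecutive steps whose improvement does not exceed `δ = 5e-4`,
reporting the best step's index (the checkpoint to retain). The
plateau controller multiplies the rate by 0.5 once the monitored loss
has failed to improve for more than `patience = 3` consecutive steps
— the first observation seeds the baseline, so under a flat loss the
first reduction lands on the 5th step — and never drops below 1e-6.

`train_reference_classifier()` exercises this whole loop at desk
scale: a multinomial logistic model over the five handcrafted
morphology features, full-batch gradient descent on class-weighted
cross-entropy with L2 decay 1e-4, LR driven by the plateau machine on
validation loss, halting by the early-stop machine, restoring the best
epoch's weights. Its default learning rate is 0.5 rather than the
1e-4 used for fine-tuning deep backbones: full-batch descent on
standardized five-dimensional features supports steps orders of
magnitude larger than minibatch deep-net training, and 1e-4 would
simply undertrain the reference model. Deep backbones remain
integration points behind the detector/classifier contracts; no
trained weights ship with the package.

## The synthetic scene generator

No synthetic data is specified upstream — the emulated study uses real
patient images — so every render parameter here is a package choice
with a single goal: give the five phenotypes archetypes that are
visually distinct and separable by handcrafted features, on scenes
that exercise the same bookkeeping as real data. The generator
emulates: the 1920×1080 frame and circular illuminated field
(radius fraction 0.45); dark cells with a thin bright rim (the
bright-field membrane halo) on a light background; a strong class
imbalance (default mixture DO 0.777, E 0.037, ES 0.142, G 0.025,
R 0.019 — the instance shares of the emulated evaluation data); about
60 cells per frame (the mean full-scope cell density); cell radii
12–18 px; a mild linear illumination gradient (4%) and Gaussian pixel
noise (sd 0.02).

Archetypes: DO is an annular disc (dark rim, brighter central pallor);
E a disc with 10 radial spicules (boundary modulation 0.22·cos 10φ);
ES an ellipse of aspect ratio 3; G a disc with dark speckles; R a disc
with a bright reticular mesh. The oracle classifier measures five
scale-invariant features — second-moment elongation, high-frequency
boundary-radius variation (detrended so smooth elongation does not
register as spiculation), dark-speckle and bright-mesh interior
fractions, and centre-minus-rim ring contrast — and scores patches
against fixed per-class centroids calibrated once on noiseless
archetype renderings.

Placement is rejection sampling: a candidate violating the box-IoU cap
(default 0.3, mirroring the copy–paste feasibility threshold) is
redrawn up to 100 times, then dropped with a warning — never an
infinite loop. Two further placement rules are deliberate: cell bodies
may not interpenetrate, and a halo-wide gap is kept between bodies.
Both reflect the physics of a blood-film monolayer (cells touch but do
not superimpose, and the bright-field halo outlines each cell) and
guarantee that every rendered cell is segmentable from its neighbours
— which is precisely what makes the oracle classifier a usable
ground-truth stand-in. Determinism is strict: the per-class counts are
the first seeded draw (`rmultinom`), per-image seeds derive from the
master seed, and identical specs give bit-identical scenes.

**What passing tests do and do not show.** The synthetic scenes have
exact boxes, noise-free labels, archetypes far more separable than
real morphologies, no staining or focus variation, no debris, and no
truly overlapping cells. Green tests therefore certify the *framework*
— IO, augmentation bookkeeping, matching, metrics, voting, schedules —
not real-data classification performance; the published benchmark
numbers that depend on trained deep networks and patient images are
inputs to the evaluation-reconstruction machinery, not claims this
package re-derives.

## Numerical choices and degenerate inputs

* Boxes touching the frame are clipped on read with a warning rather
  than rejected (edge cells exist); degenerate (zero-area) boxes are
  skipped with a log entry during cropping and flagged by validation.
* Annotation ids after any augmentation are reassigned max-id+1
  sequentially — the simplest scheme preserving COCO consistency.
* YOLO writing rounds to 6 decimals; round trips are exact to 1e-4 of
  the image dimension.
* Blank patches classify to a flagged uniform probability vector.
* The blend mask is clamped to [0, 1] after Gaussian smoothing so
  blended pixels are always convex combinations of source and target.
* Detector boxes are not expanded before classification cropping by
  default (`crop_margin = 0`, configurable): the 5 px margin belongs
  to the patch-extraction context of copy–paste, and no margin is
  specified for inference cropping.

## Problem sizes used by the tests and the acceptance script

The test suite runs on scenes of 500×400 to 800×600 px with 10–40
cells (about 70 s total); the acceptance script generates twenty
full-size 1920×1080 scenes at the default density (1,200 cells) for
the closure measurements and finishes in about half a minute on one
CPU. Brute-force oracle comparisons use 1,000 random micro-instances
of at most 6 boxes or 20 labels, where exhaustive enumeration is
cheap and exact.

## Known limitations

* The oracle classifier is tailored to the synthetic archetypes; it is
  a test oracle, not a microscopy classifier.
* Greedy confidence-ordered matching can in principle fall one pair
  short of the optimal assignment on adversarial geometry; the
  brute-force oracle in the tests quantifies this (≤ 5% of random
  micro-instances, never exceeding optimal).
* Cell tracking across frames, segmentation masks, photometric
  augmentation and GPU inference are out of scope.
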