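# rbcscope

Red blood cell (RBC) morphology is a first-line readout in sickle cell
disease: the shift from biconcave discocytes toward echinocytes,
granular cells, elongated/sickle forms and reticulocytes tracks disease
state and treatment response. Automated analysis of *full-scope*
microscopy fields — whole fields of view with hundreds of densely
packed cells — has to solve two coupled problems: localizing every cell
and assigning each one a fine-grained phenotype under severe class
imbalance (the majority class can exceed 70% of instances while the
rarest falls below 2%).

`rbcscope` implements a **decoupled detect-then-classify framework**
for this setting, aimed at computational pathology and biomedical
image-analysis researchers:

* **Two-step pipeline.** A pluggable detector localizes cells in the
  full-scope frame; each detection is cropped, padded to square with
  the local background, standardized to a fixed input size, and
  classified by an ensemble of fold-specific classifiers. Each fold
  model adds its maximum softmax confidence to the score of its
  predicted class, and the class with the largest accumulated score
  wins (confidence-weighted voting). Predictions are back-annotated
  onto the frame.
* **Imbalance-mitigation operators.** Loss level: class weights
  (inverse `w_i = N/(K n_i)`, square-root inverse, and class-balanced
  effective-number `w_i = (1-β)/(1-β^{n_i})` with β = 0.9999) and focal
  loss `FL(p_t) = -α_t (1-p_t)^γ log p_t` (α_t = 0.25, γ = 2). Data
  level: image-level oversampling with duplication factor
  `k = max(1, round(N_maj · r / N_rare))`; targeted copy–paste of
  rare-cell patches under feasibility constraints (paste centres inside
  the 0.45·min(W,H) imaging circle, IoU < 0.3 against existing boxes,
  elliptical soft-mask blending `I = I_crop·M + I_target·(1-M)`); and
  rare-class cropping (`k = 2` crops of 640×640 per rare instance with
  offsets `Uniform(-s/4, s/4)`).
* **Training-schedule state machines.** Early stopping
  (patience 7, δ = 5·10⁻⁴, best-checkpoint retention) and
  reduce-LR-on-plateau (patience 3, factor 0.5, floor 10⁻⁶) as pure,
  replayable step functions, driving a reference feature-based
  classifier trained with weighted cross-entropy under stratified
  5-fold splits.
* **Evaluation protocol.** Greedy one-to-one IoU matching,
  detection-level TP/FP/FN with `P = TP/(TP+FP)`, `R = TP/(TP+FN)`,
  `F1 = 2PR/(P+R)`, one-vs-rest per-class metrics, accuracy, macro and
  support-weighted averages, class-agnostic Recall@τ, and COCO-style
  AP/mAP (101-point interpolation, IoU 0.50:0.05:0.95).
* **Annotation IO.** COCO JSON and YOLO text readers/writers with
  full dataset validation, plus a seeded synthetic full-scope scene
  generator with five visually distinct phenotype archetypes and
  oracle detector/classifier stand-ins, so the entire pipeline is
  testable on one CPU with no dataset download and no GPU.

## Worked example

Generate a synthetic 4-image full-scope dataset, run the two-step
pipeline with a mildly degraded detector (5% misses, 1.5 px box
jitter) and the handcrafted-feature oracle classifier, and evaluate:

```r
library(rbcscope)

b <- generate_dataset(4, scene_spec(n_cells = 50), seed = 7)
print(b)
#> <scope_bundle> 4 images, 200 annotations, 5 categories
#>   instances: DO=153 E=10 ES=30 G=5 R=2

class_weights(class_counts(b), scheme = "inverse")
#>      DO       E      ES       G       R
#>  0.2614  4.0000  1.3333  8.0000 20.0000

res <- lapply(b$images, function(img) run_two_step(
  img,
  function(r) oracle_detector(r, oracle_noise(box_jitter_sd = 1.5,
                                              miss_rate = 0.05),
                              seed = r$image_id),
  list(oracle_classifier)))
preds <- do.call(rbind, lapply(res, `[[`, "predictions"))
preds$id <- seq_len(nrow(preds))
report <- build_report(bundle_annotations(b), preds, b$categories)
print(report)
#> Detection (IoU >= 0.50): Pred 193  TP 193  FP 0  FN 7  P 1.0000  R 0.9650  F1 0.9822
#> Recall@0.75: 188 / 200 = 0.9400
#> <class_metrics> n = 193
#>  category precision recall f1 support
#>        DO         1      1  1     149
#>         E         1      1  1       9
#>        ES         1      1  1      28
#>         G         1      1  1       5
#>         R         1      1  1       2
#> accuracy 1.0000 | macro F1 1.0000 | weighted F1 1.0000
#> mAP@50 0.9604 | mAP@50:95 0.7481
```

Reading the output: the detector dropped 7 of 200 cells (recall
0.9650) and box jitter pushed 12 boxes below the strict IoU ≥ 0.75
localization bar (Recall@0.75 = 0.9400); every *matched* cell was
classified into its generating phenotype (accuracy 1.0000), and the
jitter costs mAP at the tighter IoU thresholds (mAP@50:95 = 0.7481
versus mAP@50 = 0.9604). With a noiseless detector the pipeline closes
exactly: detection F1 = 1 and classification accuracy = 1.

A shell entry point wraps the same functionality
(`inst/exec/rbcscope`): `generate`, `validate`,
`augment {oversample,copypaste,rarecrop,classweights,focal}`,
`pipeline`, `evaluate`, each writing a provenance manifest with the
full configuration and seed.

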