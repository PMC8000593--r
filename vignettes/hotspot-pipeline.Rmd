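---
title: "Methods: the bone-scintigraphy hotspot detection pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the bone-scintigraphy hotspot detection pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(scintihot)
```

## The problem

Whole-body bone scintigraphy (WBBS) after Tc-99m MDP injection is the
workhorse screening examination for skeletal metastases. A scan is a pair
of planar gamma-camera projections — anterior (AP) and posterior (PA) —
acquired as one 1024 × 512 16-bit frame. Hotspots (focal regions of
elevated tracer uptake) can be metastatic, but also degenerative,
inflammatory, or traumatic; experienced readers separate them with two
dominant cues: traumatic rib hotspots line up along a rib, and
degenerative joint uptake tends to be left/right symmetric. This package
implements a complete lesion-level detection pipeline around those
observations: normalization and view fusion, offline augmentation, a
pluggable detector with an automated negative-mining training loop, and
cross-validated lesion- and patient-level evaluation. Its intended users
are methods researchers who need a fully testable, deterministic harness
for this class of pipeline.

Two scopes are deliberately out: we do not re-implement GPU-trained
one-stage neural detectors (the backend contract lets one be plugged in;
its published training hyperparameters — 150,000 iterations, batch 64,
learning rate 0.00261 — are carried as adapter metadata only), and we do
not ship clinical data. A synthetic phantom module stands in for the
cohorts.

## The phantom: what it emulates and what it does not

`generate_scan()` renders a schematic body — ellipse head/torso/pelvis,
rectangles for limbs, a spine band, six parabolic rib arcs, clavicles and
mild symmetric shoulder-joint uptake — and places three kinds of
hotspots:

* **metastases**: isolated Gaussian blobs, sigma 1.4–4.2 px, peak 3–8×
  the local background, placed in the rib-cage zone with a tight
  ground-truth box (half-width 2.2 sigma, the ~99% mass contour);
* **benign chains**: 3–5 collinear blobs spaced 15–19 px along a rib arc
  with matched intensities (post-traumatic pattern);
* **benign pairs**: an intensity-matched pair mirrored about the body
  midline near the shoulders (degenerative pattern).

Optional unboxed bladder/injection-leak blobs reproduce the classic
intensity artifacts. The global gain is sampled log-uniformly from
[0.25, 4] (so normalization does real work), Poisson noise models
counting statistics, and the PA view is the left-right mirror of the
anatomy with a slightly brighter spine and no sternum. Lesion diameters
(5–25 px boxes) are a free choice — the clinical size distribution is not
published — and the geometry is schematic, not anatomical. Passing tests
therefore demonstrate the pipeline's correctness and the mining
mechanism's effect under controlled statistics; they do not certify
clinical performance, which only the real cohorts could.

With `noise = "none"` the phantom returns expected counts as doubles, so
gain linearity is exact; `"poisson"` returns integer counts.

## Preprocessing

The body range is detected by thresholding the row/column projection
profiles at 1% of their maximum (robust to stray counts; configurable).
Each view is cut out and centered, unscaled, on a zero 512 × 950 canvas —
the guard rejects bodies larger than the canvas.

Intensity normalization controls the canvas mean into the open interval
(T₁, T₂) = (7, 14): compute the mean in double precision; if outside,
scale every pixel by (T₁+T₂)/2 divided by the mean, clip to [0, 255],
round half away from zero, and re-check. Scaling to the midpoint rather
than the nearest bound is our resolution of an under-determined design
point: it gives the largest margin against the clipping losses that drag
heavy-tailed images back below T₁, and makes the loop converge in one or
two iterations in practice (cap: 10, then a warning). The mean is taken
over the full canvas including zero background; a body-only mean would
simply shift the working range. The operation is idempotent, which the
tests exercise directly.

Chest extraction replaces a learned chest-region network with a fixed
fractional band: rows [top + 0.10·H, top + 0.45·H) of the detected body
height H, full canvas width, one rectangle for both views. It is
deterministic and places the rib cage comfortably inside the band for the
phantom geometry; the fractions are exposed for real data. We normalize
each whole-body view first and re-level the fused chest during
augmentation, consistent with the observation that pelvic uptake or
urinary artifacts can suppress chest intensity after whole-body
normalization.

## Fusion and augmentation

The fused input restores the spatial correspondence between views: red =
AP chest, green = mirrored PA chest, and the third channel is the
pixelwise product rescaled so its mean equals the mean of the two view
means. One analytic scale factor would be exact without clipping, but the
product image is heavy-tailed and clipping at 255 can move the mean by
more than the 0.5 tolerance we guarantee; the implementation therefore
re-adjusts the factor after clipping (first iteration = the analytic
factor; loop tolerance 0.2). Ground-truth boxes from the two views are
kept as separate entries and deduplicated only at evaluation time by an
IoU ≥ 0.5 same-category union-merge, since the expert merge rule is not
something we can recover.

Augmentation generates `n_levels = 6` intensity variants with target
means at the evenly spaced midpoints of (25, 48) — 26.92, 30.75, 34.58,
38.42, 42.25, 46.08 — plus a horizontal mirror of each: ×12 exactly, with
the original not additionally emitted. Midpoint spacing is our choice
where "uniformly distributed within the range" does not pin down a grid;
it keeps every achieved mean strictly inside the open interval despite
clipping and rounding (loop tolerance 0.3, well under the 3.8 spacing).
All three channels are scaled by one joint factor so channel ratios are
preserved, and box geometry is untouched.

## The reference detector

The detector backend is a contract: `fit_detector()` consumes labeled
fused images, `detect_hotspots()` emits category/confidence boxes. The
reference implementation is deliberately classical so the whole pipeline
trains on one CPU in seconds per cohort:

* **Proposal**: difference-of-Gaussians (ratio 1.6) at sigmas
  {2, 3, 4.5} on the pixelwise channel maximum; 8-neighbour local maxima
  above a response threshold of 3 become candidates. Box size comes from
  classic scale selection — the sigma-normalized response across scales
  picks the best scale, and the blob sigma is ≈ 0.85 of it — which keeps
  candidate boxes within IoU 0.3 of tight ground truth across the whole
  lesion-size range. Candidates need peak contrast ≥ 10 over a 2-px ring,
  and cross-scale duplicates are suppressed (IoU > 0.5 or
  center-containment), capped at 120 per image.
* **Features** (16): per-channel interior mean/max/variance, ring
  contrast, aspect and log-area, a mirror-symmetry correlation and
  intensity balance against the left-right mirrored location, and
  collinearity/crowding counts over the other candidates — direct
  encodings of the clinical cues above.
* **Classifier**: ridge multinomial logistic regression (glmnet,
  lambda = 0.01) over background plus 1 or 2 hotspot categories, with
  class-balancing observation weights (exponent 0.5) because candidates
  are overwhelmingly background; the calibrated class probability is the
  confidence. Ground-truth boxes are added as positive examples next to
  the IoU ≥ 0.3-matched candidates, and a floor of 5 background examples
  per image is kept (seeded sampling). Training is bit-reproducible for a
  fixed seed.

Fine-tuning (`transfer_finetune()`) fits a second coefficient block with
a stronger ridge penalty (lambda 0.05) on top of the pre-trained linear
predictor supplied as an offset: the pre-trained model is the
initialization and prior, and the update moves away from it only as far
as the target data warrants — the classical analogue of warm-started
fine-tuning.

## Negative mining

The training loop is: (1) pre-train a one-class metastasis detector on
positives only; (2) run it on images known to be metastasis-free with the
confidence floor at 0.1 — every detection strictly above the floor is by
construction a false positive — and relabel those boxes as a
`normal_hotspot` class; (3) retrain with both classes; (4) fine-tune on
the target cohort, folding the scarce equivocal annotations into the
normal group for training (a switch allows ignoring them instead, which
is what evaluation does). Mining never mutates label files: mined boxes
live in a provenance-tracked store (model digest, threshold) merged only
at training time.

The paired experiment in the acceptance suite quantifies the effect under
the phantom's statistics: same seeds and the same training budget, a
60-phantom target cohort, fine-tuned-after-mining versus trained on the
target folds alone. Median held-out lesion precision improves markedly
with mining (the benign patterns harvested from the normal cohort teach
the second class), which is the mechanism the workflow exists for.

## Evaluation

Box matching is greedy in descending confidence (ties: ascending x, then
y): a detection claims the unmatched same-category ground-truth box of
highest IoU ≥ 0.3; failing that, an overlapping unmatched equivocal box
absorbs it (neither TP nor FP, box consumed); otherwise it is a false
positive. Unmatched non-equivocal ground truth is a false negative;
equivocal boxes never are. Greedy matching with these tie-breaks equals
exhaustive optimal assignment on all instances with ≤ 2 detections and on
well over 95% of random small instances — both checked against a
brute-force oracle. Lesion-level metrics are sensitivity and precision
(true negatives are undefined per-lesion); undefined ratios are reported
as NA and excluded from aggregation with a warning, never silently
treated as zero. The patient-level call is "≥ 1 metastasis detection with
confidence > 0.5" (the decision threshold is exposed, as no published
rule exists), giving sensitivity and specificity.

Cross-validation follows the shuffle design: each shuffle re-randomizes a
stratified split (positives and negatives shuffled independently, dealt
round-robin into k folds), holds out fold 1, fine-tunes on the augmented
remainder and evaluates the held-out fold; `full_cv = TRUE` rotates
through all folds instead, for readers who interpret one shuffle as a
complete k-fold pass. Aggregates are the mean and the sample (n−1)
standard deviation, rendered at two decimals with half-away-from-zero
rounding; the bundled 10-shuffle reference tables reproduce their printed
Average rows exactly under this rule (the printed ± values are consistent
with the sample convention for most but not all columns, which is why the
package documents and emits sample SD).

## Problem sizes, determinism, and limits

The shipped configurations are desk-scale by design: the demonstration
pipeline uses a 10+10 phantom pre-train cohort, an 8+8 target cohort, 2
shuffles with k = 4 and a ×4 augmentation plan; the acceptance sweeps use
500 phantoms for normalization/augmentation properties, 200 for fusion,
1000 random instances for each geometry oracle, and five paired seeds
(15+15 pre-train, 60-phantom target, k = 5, ×2 augmentation) for the
mining experiment. Every stochastic step is seeded — phantom rendering,
fold shuffling, background sampling — and the pipeline replays
bit-identically from its configuration.

Known limitations: the phantom is schematic (no attenuation, scatter,
SPECT, or anatomy beyond left/right symmetry and a chest band); the
chest band is a rule, not a learned detector; DICOM input is not decoded
in this build (16-bit TIFF is the canonical interchange); superscan
exclusion and expert adjudication are upstream clinical steps; and the
reference detector is a baseline meant to exercise the pipeline contract,
not a competitor to trained one-stage networks.
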