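---
title: "Methods: phantom-based myometrial invasion staging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantom-based myometrial invasion staging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

FIGO stage I endometrial carcinoma is split at surgery into stage IA
(myometrial invasion below 50% of the myometrial thickness) and stage IB
(invasion of 50% or more). Pre-operative staging reads this fraction from
sagittal MR images, and discrepancies between the image-based call and the
post-operative pathological stage drive over- and under-treatment. The
pipeline in this package mirrors a machine-reading workflow for that task:
segment the uterus and the endometrial lesion on a sagittal slice, convert
the two masks into an invasion-depth fraction, call IA/IB at the 50%
cutoff, and run the concordance statistics that compare a machine reader
with radiologists.

Patient MRI from the motivating cohort is institutional and cannot ship
with code. The package therefore includes a synthetic phantom generator
whose geometry carries an analytically known invasion fraction, so every
downstream stage can be validated against ground truth. The printed
summary tables of the motivating study (contingency counts of staging
calls) ship as a plain-text fixture and are reproduced exactly by the
statistics module; everything image-based is validated on phantoms.

## The phantom generator

A phantom is a 2-D sagittal-like cross-section built from radial curves
around the uterine centre:

* the **serosa** (outer uterine boundary) is an ellipse with semi-axes
  defaulting to `0.38` and `0.30` of the canvas (default canvas 128 px;
  896 px is supported to mirror full-resolution work);
* the **endomyometrial junction** is a smooth trigonometric curve
  `r_j(theta) = r0 (1 + sum_k a_k cos k theta + b_k sin k theta)` of order
  at most 3, with `r0 = 0.45 * min(axes)`. A low-order junction is a
  modelling choice that makes the staging estimator's smooth-baseline
  assumption well-posed;
* the **lesion** occupies the cavity plus a raised-cosine radial
  protrusion over an angular sector (default width drawn from
  `[pi/4, pi/2]`): at sector centre the lesion reaches
  `r_j + f * (r_s - r_j)` where `f` is the target invasion fraction;
* an optional **leiomyoma** is a disc centred mid-myometrium that locally
  bulges the serosa outward and dents the junction inward (mass effect).
  The dent is the confounding mechanism: a local junction deformation that
  a low-order fit cannot track, which is what degrades staging accuracy on
  leiomyoma-bearing phantoms at matched fractions.

Tissue classes are painted with per-modality mean intensities
(`default_intensity_table()`): on the contrast-enhanced T1w-like channel
the myometrium enhances and the lesion is dark; on the T2w-like channel
the lesion is bright and the leiomyoma markedly dark. Additive Gaussian
noise (sd 0.05 by default, intensities on a unit scale) stands in for
acquisition noise; no attempt is made to model MR physics (bias fields,
partial-volume effects, sequence parameters), 3-D anatomy, or multi-slice
stacks — a case is one slice, and `stage_case()` accepts per-slice
fraction vectors for multi-slice use.

**Recorded truth.** The invasion fraction is defined as the ray-maximum of
`(r_lesion - r_junction) / (r_serosa - r_junction)` — deepest penetration
over local myometrial thickness. The recorded `true_fraction` evaluates
this on the angular grid including the sector centre, where it equals the
target fraction exactly; the stage label follows the inclusive rule
(`fraction >= 0.5` is IB, since the IB-side row of the source tables reads
"at least 50% invasion" while prose leaves exactly-50% open). An
exhaustive per-angle scan of the emitted masks recovers the recorded value
to within 0.01 at a 192-px canvas and within 0.02 at the default 128 px;
the gap is pixel-quantization of the mask boundary (about half a pixel on
a myometrium roughly 20 px thick), not a bookkeeping discrepancy.

**Cohort composition.** Defaults emulate the motivating cohort: 26.4%
stage IB, 40.3% leiomyoma prevalence, 18% type-II histology (a covariate
label only), with per-stage fraction laws uniform on `[0, 0.48]` (IA) and
`[0.5, 0.87]` (IB), bounded by the observed five-number ranges. Stage and
leiomyoma status are independent binomial draws, so realized counts
fluctuate around the expectation and converge as the cohort grows.

## Preprocessing

Standardization is the pixel-wise transform `(P - mean) / sd` over the
whole image with the population (denominator `n`) standard deviation —
the formula names the statistics of *all* pixels, and either denominator
convention fits; population is chosen and pinned by test. It is applied
per image (a per-dataset variant would only shift a global affine factor
and is not implemented). `crop_resize()` center-crops to the largest
square and resamples (bilinear for images, nearest for masks, so masks
stay binary).

Augmentation emits the original, horizontal and vertical flips, a random
small affine (rotation up to 15 degrees, translation up to 5%, isotropic
scale 0.9–1.1) and an intensity-scaled copy (factor 0.8–1.2). The source
protocol lists "multiplying" among its augmentations without definition;
it is read here as intensity scaling, and dataset replication can be
emulated by calling `augment()` with several seeds. Every emitted pair
carries a provenance tag, and the experiment runner only ever augments
the training pool — derived images never reach validation or test.

Splitting mirrors the study design: one third of cases train the model, a
6-case validation group drives checkpoint selection, and the remainder is
the test group. The cohort-faithful evaluation pool includes the
validation cases (as the source protocol did: 42 test plus 6 validation
cases were appraised); `evaluation = "strict"` restricts scoring to the
disjoint test group, and reports state which pool was used.

## Segmentation network

`build_model()` constructs an encoder–decoder (U-Net style) network with
equal numbers of down- and up-sampling stages, skip connections between
opposing stages, and one sigmoid output channel per structure (uterus and
lesion as independent channels rather than exclusive softmax classes,
because the two structures are labelled separately and overlap: the
lesion lies inside the uterus; containment is enforced after
thresholding). Encoder presets `vgg11-like`, `vgg16-like` and
`resnet34-like` follow the depth/width patterns of their namesakes at
reduced channel counts; the `tiny` preset (depth 3, 8 base channels, one
decoder conv per stage, about 110k parameters) is the CPU desk-scale
variant used in tests. No pretrained weights ship with the package;
all encoders initialize randomly (He-scaled), which diverges from the
ImageNet-pretrained encoders of the motivating study and is one reason
desk-scale IoU bars are set at artifact level (0.80 uterus / 0.60 lesion)
rather than at the study's patient-data values.

The network and its backpropagation are implemented directly in R: 3x3
convolutions are im2col gathers followed by BLAS matrix products, pooling
and nearest-neighbour upsampling are index maps, and gradients are exact
(verified against finite differences in the test suite). This keeps the
whole pipeline dependency-light and deterministic on a single CPU thread.

Training is plain SGD with momentum 0.9 (configurable; the source
protocol states only "stochastic gradient descent") on the soft-Dice loss
`1 - (2 sum(p t) + 1) / (sum p + sum t + 1)`; the smoothing constant 1 is
a design choice pinned by test, and Dice is preferred over cross-entropy
for its robustness to the small-structure/background imbalance. Batch
gradients are clipped to a global norm of 1 before the momentum update:
the Dice loss has a failure mode where one overshooting step saturates
every output sigmoid towards zero, after which the gradient vanishes with
`p(1 - p)` and the network cannot recover; clipping removes that
seed-dependent collapse without changing well-behaved trajectories.
`train_config()` defaults to the study protocol (batch 16, learning rate
0.001, 150 epochs); the desk-scale tests use batch 4, learning rate 0.05,
15 epochs — chosen once for the easy phantom contrast, where the paper's
settings are tuned for patient images and GPU-scale budgets. Per-epoch
training loss, validation loss and validation IoU are logged; the
returned checkpoint is the epoch with the smallest validation loss, not
the last epoch. A non-finite loss aborts with a divergence diagnostic.

## Staging estimator

The source study never states how invasion depth was computed from
segmentations, so the measurement geometry is an explicit package
decision, used identically for phantom truth and for estimation:

1. `ray_profile()` casts rays (default 720) from the centroid of the
   lesion's erosion-stable core and records the outermost lesion and
   uterus crossings per angle (nearest-neighbour sampling, 0.25 px step).
2. `estimate_junction()` reconstructs the pre-invasion junction by a
   trigonometric fit (order <= 3) to the lesion radius with iterative
   down-weighting of positive residuals — the protrusion is treated as an
   outlier above a smooth baseline, while negative residuals keep full
   weight. The robust scale is the MAD, floored at 0.5 px; ten
   iterations are ample in practice.
3. `invasion_fraction()` computes per-ray
   `max(0, r_lesion - r_junction_hat) / (r_serosa - r_junction_hat)`,
   excludes rays with residual thickness below 2 px (degenerate), smooths
   the per-ray curve with a 5-ray circular moving average (about 2.5
   degrees; suppresses single-ray rasterization spikes that would bias a
   raw maximum upward), takes the maximum and clamps to `[0, 1]`.
4. `stage_case()` aggregates slices by the maximum (deepest invasion
   governs) and applies the inclusive 50% cutoff.

Holding the junction fixed, the fraction is exactly monotone in the
lesion mask; re-estimating the junction after enlarging the lesion can
shift the baseline by a fraction of a pixel, so end-to-end monotonicity
holds to about 0.01. Estimates are exactly equivariant under 90-degree
rotations (the pixel grid maps onto itself). On 200 leiomyoma-free
phantoms with fractions uniform on `[0, 1]`, estimation from ground-truth
masks achieves RMSE of about 0.014 and stage agreement above 95%; these
are the package's acceptance bars (RMSE <= 0.05, agreement >= 95%).

## Statistics

The concordance module wraps standard machinery behind the staging
vocabulary: `diagnostic_summary()` (accuracy, over-/under-diagnosis rates
as fractions of the incompatible cases), `pearson_chi2()`
(`chisq.test(correct = FALSE)`; the uncorrected Pearson statistic
reproduces every matching printed value, so no Yates correction is
applied — pinned by test), `pearson_correlation()` (`cor.test`),
`oneway_anova()` (linear-model decomposition), and
`five_number_summary()` (type-7 linear-interpolation quartiles,
convention switchable since the source software's default is unknown).

`reproduce_printed_tables()` recomputes all 28 derivable quantities from
the printed contingency counts shipped in
`inst/extdata/printed_counts.yaml` and compares each against its printed
value at printed precision with round-half-even. Five printed values do
not reproduce from their own printed counts (a chi-square of 0.738
recomputing to 0.741 with p 0.392 vs 0.389; a leiomyoma-effect p of 0.115
recomputing to 0.116; one accuracy printed 56.3 where the counts give
56.25; and a histology-effect p printed 0.727 where the counts give
0.948). These are reported with `match = FALSE` rather than forced: the
discrepancies live in the source material (rounding conventions or
software variance) and cannot be resolved from the printed counts alone.

The study's segmentation IoU values (94.20%/79.16% on contrast-enhanced
T1w, 91.66%/79.31% on T2w), its correlation coefficients (r = 0.54/0.52)
and ANOVA F statistics (99.06/44.46/17.68) require the institutional
per-patient data and are **not** reproduction targets; the corresponding
operations are instead validated on synthetic data by the property tests.

## The experiment runner

`run_experiment()` chains cohort generation, splitting, standardization,
training-pool augmentation, training with checkpoint selection,
prediction on the evaluation pool, ray-based staging and the concordance
report, with every stage seeded from the global seed (distinct stage
offsets keep RNG streams independent) and a manifest listing the written
artifacts. Identical configuration and seed give identical outputs in
single-threaded mode. Cases round-trip to disk as NIfTI images plus PNG
masks (0/255 and 0/1 encodings both normalize to binary on read) and CSV
truth tables.

## Problem sizes and runtime choices

The shipped tests and the acceptance script use desk-scale sizes chosen
to exercise every claim on one CPU: 128-px phantoms, 200-case recovery
cohorts, 60-training-case learning runs of 15 epochs, and a 24-case
end-to-end smoke experiment of 5 epochs. The 192-px canvas appears only
in the truth-recovery oracle test, where rasterization error at 128 px
would dominate the comparison. Full-scale settings (896-px canvas, batch
16, 150 epochs) are expressible through the same configuration objects.

## What passing tests do and do not show

Phantoms are star-shaped, single-slice, two-class geometries with
Gaussian noise; real uteri are none of these. Passing the recovery and
learning bars shows that the pipeline's geometry, optimization and
statistics are internally correct and that the invasion-fraction
definition is recoverable end-to-end — it does not certify performance on
patient MRI, where boundary contrast, anteverted/retroverted shape
variation, adenomyosis and polypoid growth patterns dominate difficulty.
The leiomyoma experiment reproduces the *direction* of the published
confounder effect (lower staging accuracy with leiomyoma at matched
fractions), not its magnitude.
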