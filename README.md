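# myoinvade

Pre-operative staging of stage-I endometrial cancer asks one quantitative
question of a sagittal MR image: how deep does the endometrial lesion
penetrate the myometrium, as a fraction of the local myometrial thickness?
Below 50% the case is FIGO stage IA, at or above 50% it is IB, and the
answer steers surgical radicality and lymphadenectomy. `myoinvade`
implements a machine-reading pipeline for that question, end to end, for
researchers studying image-based staging concordance:

* a **synthetic phantom generator** producing sagittal uterine
  cross-sections (serosa, endomyometrial junction, invading lesion,
  optional leiomyoma) in two MR-like contrasts, with an analytically known
  invasion fraction — a shareable stand-in for institutional patient MRI;
* **preprocessing** faithful to the protocol it emulates: per-image
  standardization `P' = (P - mean) / sd`, center-crop/resample,
  flip/affine/intensity augmentation (training pool only), and the
  one-third / 6-case / remainder train–validation–test split;
* an **encoder–decoder segmentation network** (U-Net style; `tiny`,
  `vgg11-like`, `vgg16-like`, `resnet34-like` presets) trained with SGD on
  the soft-Dice loss, with best-validation-loss checkpointing and IoU
  evaluation — implemented directly in R on BLAS matrix products, exact
  gradients verified by test;
* a **staging estimator** that casts rays from the lesion core, robustly
  reconstructs the pre-invasion junction with a low-order trigonometric
  fit, and converts the uterus/lesion masks into the invasion fraction
  `max_theta (r_lesion - r_junction) / (r_serosa - r_junction)`, calling
  IA/IB at the inclusive 50% cutoff;
* the **concordance statistics** of the motivating study: accuracy,
  over-/under-diagnosis rates, uncorrected Pearson chi-square, Pearson
  correlation, one-way ANOVA, five-number summaries — plus an exact
  reproduction of the published tables from their printed contingency
  counts (`reproduce_printed_tables()`).

Results are tibbles throughout, fitted objects have broom-style `tidy()` /
`glance()` methods, and result types have `autoplot()` /
`plot_fraction_by_concordance()` ggplot2 helpers.

## Worked example

Generate a small cohort, stage it from ground-truth masks, and summarize
concordance:

```r
library(myoinvade)

cohort <- generate_cohort(cohort_spec(n_cases = 40, seed = 7))
cohort
#> <phantom_cohort> 40 cases (31 IA / 9 IB), 16 with leiomyoma

staged <- stage_cohort(cohort)          # ray-based estimate per case
truth  <- cohort_truth(cohort)
diagnostic_summary(staged$stage, truth$true_stage)
#> # A tibble: 1 × 8
#>       n n_compatible n_over n_under accuracy over_diagnosis_rate
#>   <int>        <int>  <int>   <int>    <dbl>               <dbl>
#> 1    40           40      0       0        1                   0
#> # ℹ 2 more variables: under_diagnosis_rate <dbl>, rates_defined <lgl>
```

Forty clean phantoms staged from their own ground-truth masks are all
called correctly — the estimator's error (RMSE about 0.014 in fraction
units) only flips calls when the true fraction sits within a couple of
percent of the 50% cutoff. The published contingency tables reproduce
from their printed counts:

```r
rep <- reproduce_printed_tables()
rep
#> <printed_tables_report> 28 quantities recomputed, 23 match printed values
#>   printed values not reproducible from their own printed counts:
#>     chi2_ai_t2_vs_radiologists: computed 0.7407, printed 0.738
#>     p_ai_t2_vs_radiologists: computed 0.3894, printed 0.392
#>     accuracy_ai_t2_with: computed 56.25, printed 56.3
#>     p_leiomyoma_ai_t2: computed 0.116, printed 0.115
#>     p_histology_ai_t2: computed 0.948, printed 0.727
dplyr::filter(rep, quantity == "accuracy_ai_t1c")$computed
#> [1] 79.16667
```

The 79.2% / 70.8% / 77.8% accuracies, the chi-square 0.033 (p = 0.856)
against the radiologists, and the leiomyoma-effect p = 0.027 all
recompute exactly; the handful of printed values that disagree with their
own printed counts are reported, not forced. A full experiment — phantoms
through training through staging through report — is one call:

```r
cfg <- experiment_config(
  cohort   = cohort_spec(n_cases = 24, seed = 7),
  training = train_config(batch_size = 4, learning_rate = 0.05,
                          epochs = 5, seed = 7),
  seed = 7
)
res <- run_experiment(cfg)
res$report
```

## Scope

Phantoms are 2-D single-slice geometries with Gaussian noise; the package
does not simulate MR physics, 3-D anatomy, DICOM ingestion, or
pretrained-encoder transfer, and the motivating study's patient-data IoU
and correlation values are out of reach by construction (its images are
institutional). See `vignettes/methods.Rmd` for the model, the
measurement geometry, parameter defaults and their rationale, and known
limitations.
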