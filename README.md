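# perfcad

Single-subject computer-aided detection of Alzheimer-type hypoperfusion
from arterial spin labeling (ASL) cerebral blood flow maps.

## What it does, and for whom

Group-level voxel-based statistics can show *that* AD cohorts are
hypo-perfused in the parietal lobe and limbic system; a clinician needs to
know whether *this* patient is. perfcad takes spatially normalized,
partial-volume-corrected CBF volumes (one per subject, common 2 mm grid),
per-subject gray-matter probability maps, an integer brain atlas and a
clinical table, and produces for each subject a probabilistic
hypoperfusion map, a binary HC/AD call with an explicit operating point,
and a per-region account of where the hypoperfusion sits. It is intended
for methods researchers working on ASL-based normative modeling; it is
not a medical device.

Because no clinical ASL cohort of this kind is publicly distributable,
the package ships a synthetic cohort generator that plants multiplicative
lesions in designated atlas regions, so the entire pipeline is testable —
and every number below is computed — without any data download.

## The model

For healthy controls, each masked voxel *j* gets a Gaussian
N(&mu;<sub>j</sub>, &sigma;<sub>j</sub>) (population SD, divisor
N<sub>HC</sub>). A test subject's likelihood of deviant perfusion is the
upper-tail survival probability

&nbsp;&nbsp;&nbsp;&nbsp;L<sub>j</sub> = 1 − &Phi;((x<sub>j</sub> − &mu;<sub>j</sub>)/&sigma;<sub>j</sub>)

(0.5 = normal, →1 = hypo-, →0 = hyper-perfusion). Two priors temper L and
the posterior is their weighted mean

&nbsp;&nbsp;&nbsp;&nbsp;P = M<sup>−1</sup> &Sigma;<sub>m</sub> L ∘ &pi;<sub>m</sub>,&nbsp;&nbsp; M = 2:

the gray-matter probability &pi;<sub>GM</sub> (WM ASL signal is
unreliable) and a disease-predictive weight &pi;<sub>PP</sub> from
ordinary least squares of the group code (HC → −1, AD → +1) on stacked
likelihood vectors, solved in a PCA-reduced space via the Gram-matrix
trick (eigenpairs of N<sup>−1</sup>XX<sup>T</sup>, first K = 20
components, coefficients back-projected and min–max rescaled to [0, 1]).

A voxel is hypo-perfused when P ≥ t<sub>w</sub>; a subject is AD when its
hypo-voxel count exceeds t<sub>b</sub>. Both thresholds come from an
exhaustive grid search minimizing misclassification under leave-one-out,
with the healthy model and &pi;<sub>PP</sub> refit in every fold. An RBF
max-margin classifier on the held-out posteriors is included for
comparison, and hypo-voxel counts are accumulated per atlas region and
correlated with MMSE, age and education.

## Worked example

```r
library(perfcad)
co  <- generate_cohort(synthetic_cohort_spec())   # 30 HC + 30 AD, 24x24x12, lesion effect 0.70, seed 42
run <- run_pipeline(co$volumes, co$gm, co$clinical, co$atlas)
print(run)
```

```
<perfcad_run> J = 4096 voxels, input hash afa2cf1d
<loo_result> 60 folds: sensitivity 0.967, specificity 0.967, misclassification 0.033
  modal thresholds t_w = 0.91, t_b = 50 (frequency 0.18)
  svm: accuracy 1.000, sensitivity 1.000, specificity 1.000
  correlations (correctly classified patients):
  covariate    rho p_value  n
1      mmse -0.539 0.00256 29
2       age  0.204 0.28856 29
3 education  0.370 0.04793 29
```

Reading it: of 6912 grid voxels, 4096 survive the 0.95 coverage mask.
Leave-one-out, 58 of 60 synthetic subjects are classified correctly; the
modal fold-chosen operating point is t_w = 0.91, t_b = 50 (the published
clinical operating point was t_w = 0.86, t_b = 200 on a far larger brain
volume — thresholds scale with the world). The kernel classifier
separates this phantom perfectly. The hypo-perfused volume correlates
inversely with MMSE (&rho; = −0.54) because the generator couples MMSE to
lesion burden; age and education are uncoupled, and behave accordingly.

```r
run$regional$summary[, c("name", "mean_hc", "mean_ad", "fraction_pooled", "p_value")]
```

```
          name mean_hc mean_ad fraction_pooled  p_value
1      frontal    0.00     0.0           0.000 1.00e+00
2     parietal    2.60    51.4           0.595 3.57e-11
3     temporal    0.00     0.0           0.000 1.00e+00
4       limbic    1.67    35.1           0.405 1.35e-11
5 white_matter    0.00     0.0           0.000 1.00e+00
6   background    0.00     0.0              NA 1.00e+00
```

All detected hypoperfusion falls in the two planted disease regions
(parietal 59.5%, limbic 40.5% of hypo voxels), with strongly significant
group differences there and nowhere else.

Single-subject scoring against a fitted model:

```r
res <- classify_volume(volume, gm, model, pp, mask, t_w = 0.86, t_b = 200, atlas = atlas)
res$label   # "AD" or "HC"
res$count   # hypo-perfused volume in voxels
```

A command-line interface with `simulate` / `evaluate` / `classify`
subcommands is installed at `inst/scripts/perfcad` (run it with
`Rscript`); volumes are NIfTI-1 (`.nii`/`.nii.gz`), the clinical table is
CSV (`id,group,age,mmse,education,gender`), atlas name maps are TSV, and
configs are YAML or JSON.

## Layout

* `R/` — volume/mask/NIfTI I/O, post-processing, healthy model,
  likelihood/priors/posterior, PCA-regression prior, discriminant +
  SVM, regional analysis, synthetic generator, pipeline orchestration.
* `vignettes/perfusion-cad.Rmd` — the methods vignette: model,
  assumptions, parameter table, what the phantom does and does not
  emulate, numerical choices, limitations.
* `tests/testthat/` — unit, property and acceptance tests.
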