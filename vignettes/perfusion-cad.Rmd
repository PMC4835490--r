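---
title: "Normative perfusion modeling and single-subject hypoperfusion detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative perfusion modeling and single-subject hypoperfusion detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perfcad)
```

## The problem

Arterial spin labeling (ASL) measures regional cerebral blood flow (CBF,
ml/100 g/min) without contrast agents or ionizing radiation. In
Alzheimer-type dementia, perfusion is characteristically reduced in the
parietal lobe and limbic structures, which makes CBF maps a candidate
biomarker — but ASL maps are noisy, and group-level voxel-based
statistics do not answer the clinical question, which is about *one*
patient. perfcad implements a single-subject computer-aided diagnostic
procedure: a voxel-wise normative model of healthy perfusion, a
probabilistic comparison of one subject against it, prior-based
suppression of known artifact sources, and a transparent two-threshold
decision rule, plus atlas-based regional accounting that keeps the result
anatomically interpretable.

The package consumes CBF volumes that are already quantified, spatially
normalized to a common 2 mm grid, and partial-volume corrected; all MR
physics and registration are upstream and out of scope.

## The model

**Post-processing.** Each volume is smoothed with a separable, truncated
Gaussian kernel (sigma = 2 voxels, window extent 6; the realized window is
7^3 taps, renormalized to sum 1, zero-padded at boundaries), then
feature-scaled per volume by min–max over the analysis mask. Min–max
scaling is invariant to positive affine transforms of the input, which is
exactly the property needed to remove globally reduced CBF (cardiovascular
state) and scanner-dependent labeling efficiency before any
between-subject comparison. Analysis is restricted to voxels where the
fraction of subjects with nonzero signal strictly exceeds 0.95 (partial
scan coverage is the norm in pulsed ASL); masked volumes are linearized to
vectors over a fixed voxel ordering.

**Healthy reference.** At each masked voxel j the healthy controls define
a Gaussian N(mu_j, sigma_j), with sigma the *population* form (divisor
N_HC, as the reference equations are printed; a sample-SD switch exists).
Zero-variance voxels are floored at `1e-6 * max(sigma)` so standardization
is always defined. T-score maps (x - mu)/sigma support visual reading.

**Likelihood and posterior.** The likelihood of deviant perfusion is the
complementary cumulative Gaussian, `L = 1 - pnorm((x - mu)/sigma)`: 0.5 is
normal, values near 1 are hypo-perfusion, values near 0 hyper-perfusion.
Two priors temper L, and the posterior is their prior-weighted mean,
`P = mean_m(L * pi_m)`:

* `pi_GM` — the subject's gray-matter probability map (WM ASL signal is
  unreliable; low-GM voxels are suppressed);
* `pi_PP` — a disease-predictive weight per voxel, obtained by ordinary
  least squares of the group code (HC = -1, AD = +1) on the stacked
  likelihood vectors, solved in a PCA-reduced space because J >> N. The
  PCA uses the Gram-matrix identity: eigenpairs of `N^-1 X X^T` (N x N)
  are mapped to voxel space by `u_j = (N lambda_j)^(-1/2) X^T v_j`. The
  first K = 20 components are used (capped at N - 1 on small cohorts),
  and the back-projected coefficients `beta = U beta'` are min–max
  rescaled to [0, 1].

Note `P <= L` element-wise always: priors can only remove evidence, never
add it.

**Decision rule.** A voxel is hypo-perfused when `P >= t_w` (inclusive); a
subject is classified AD when the hypo-voxel count strictly exceeds
`t_b`. Both thresholds are chosen by exhaustive grid search
(t_w in 0.50–1.00 by 0.01, t_b in 0–5000 by 50, configurable) minimizing
the misclassification rate, with ties broken by maximal
sensitivity + specificity, then smallest t_b, then largest t_w.
Evaluation is leave-one-out: every fold refits the healthy model (without
the held-out subject when it is a control), refits `pi_PP` without it,
re-runs the grid search on the remaining subjects only, and classifies the
held-out subject. Pooled fold predictions give the reported rates; the
modal threshold pair across folds is reported alongside, as are the rates
obtained by applying the modal pair to all held-out posteriors — the
published operating point (t_w = 0.86, t_b = 200) is of the modal kind,
and which of the two readings a published rate refers to is genuinely
ambiguous, so both are emitted. An RBF max-margin classifier (C-SVC dual
solved with quadprog; gamma = 1/J, cost = 1, both configurable and
excluded from any accuracy claim) runs on the same held-out posteriors.

**Regional analysis.** Hypo-voxel calls are accumulated over an integer
atlas; regions not fully inside the coverage mask are flagged and excluded
from fraction summaries. Group differences per region use the two-sided
Mann–Whitney test (the field's p-values for skewed counts; Welch t by
flag, Bonferroni optional), and the hypo-perfused volume is correlated
with MMSE, age and education by Spearman's rho over the correctly
classified patients. Region fractions are emitted in both defensible
readings: mean of per-subject fractions and pooled voxel fractions.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| smoothing sigma | 2 | voxels (4 mm at 2 mm grid) | published operating point; ASL noise suppression |
| kernel extent s | 6 | voxels | published; realized as a centered 7^3 window |
| coverage threshold | 0.95 | fraction | strict `>`; equal-or-less coverage is discarded |
| K components | 20 | — | published; capped at N - 1 per training fold |
| t_w grid | 0.50–1.00 / 0.01 | probability | published evaluation range |
| t_b grid | 0–5000 / 50 | voxels | published range; rescale for small grids |
| sigma floor | 1e-6 · max(sigma) | relative | keeps standardization defined at degenerate voxels |
| SVM gamma, cost | 1/J, 1 | — | common heuristics; unreported upstream, no claims attached |

## The synthetic world

No clinical cohort is distributable, so the generator builds one with the
statistical structure the pipeline assumes. The toy brain is a
superellipsoid containing a white-matter matrix (baseline 20 ml/100g/min)
with four embedded gray-matter structures (baseline 60): frontal,
parietal, temporal, limbic. Parietal and limbic are the designated disease
regions (~900 voxels on the default 24 x 24 x 12 grid). Per subject,
`volume = baseline + offset + noise` inside the brain, with a global
subject offset N(0, 8) and voxel noise N(0, 6); AD subjects multiply the
composed value in the disease regions by a severity drawn around the
lesion effect (default 0.70, jitter SD 0.06, clamped to [0.4, 1]). GM
probability maps are ~0.95 / ~0.05 in GM / WM. Ages echo a memory-clinic
cohort (early-onset ~60, late-onset ~74, controls ~66); MMSE is ~29.5 for
controls and decreases linearly with lesion burden, calibrated so the
default severity costs about 7 points — a qualitative analogue of the
strong inverse burden–MMSE correlation seen clinically, not a numeric
target.

Design choices worth stating:

* **GM structures are embedded in WM** rather than adjacent to each
  other, mirroring the fact that cortical parcels are bounded by WM/CSF.
  A consequence is that smoothing bleed from a lesion lands in low-GM
  tissue, where the GM prior suppresses it — which is precisely that
  prior's job on real data.
* **Gaussian, not Rician, noise**: the pipeline consumes smoothed,
  partial-volume-corrected CBF maps whose residuals are approximately
  Gaussian; MR magnitude statistics belong upstream.
* **What a green test does not establish**: the phantom has no motion,
  no transit-time artifacts, no scanner mix, no atrophy confound, and its
  lesions are spatially exact. Passing end-to-end tests demonstrates the
  machinery is correct and self-consistent, not that clinical accuracy
  figures transfer.

## Numerical and design notes

* **Voxel ordering** is R's native column-major array order (x fastest),
  fixed and deterministic; any fixed bijection is equivalent, and this is
  the idiomatic one for R arrays.
* **Population vs sample SD**: the reference equations use divisor N_HC;
  implemented as printed, `sd_divisor = "n-1"` available.
* **The OLS normal-equation formula** in the source material is
  typeset corruptly; the surrounding prose ("ordinary least squares") is
  implemented, with a pseudoinverse fallback for rank-deficient designs.
* **Beta rescaling to [0, 1]** is min–max by default (negative,
  health-predicting voxels land near 0 and are down-weighted); `"abs"`
  and `"clip"` variants are available since the exact map is unstated
  upstream.
* **Boundary conventions** are declared and tested: voxel test inclusive
  (`P >= t_w`), subject test strict (`count > t_b`), coverage strict
  (`> 0.95`).
* **Coverage is computed on raw input volumes**, before smoothing;
  whether the original procedure did this before or after smoothing is
  unstated.
* **Feature scaling** is interpreted literally as min–max over masked
  voxels; a global-mean division is available behind a flag, and both are
  computed within the mask by default (whole-grid statistics would be
  dominated by background zeros).
* **Statistical acceptance checks** use multiplicity-aware bounds: a
  per-voxel criterion at k standard errors is asserted up to the exact
  binomial envelope over voxels, plus an RMS bound at the 1/sqrt(n)
  scale. A literal "every voxel within 2.24 SE" reading would fail for a
  perfectly correct estimator on most seeds.
* **NIfTI-1 input/output** is a minimal self-contained reader/writer
  (base R `readBin`/`writeBin`; `.nii` and `.nii.gz`; float/int ingest
  with `scl_slope` handling) because no NIfTI package is available in the
  target environment. It handles the single-file 3D case this pipeline
  needs and nothing more.

## Known limitations

* No covariate adjustment (age, sex) in the normative model; the clinical
  motivation is real but out of scope here.
* Hyper-perfusion (L near 0) is computed but never classified.
* The atlas must already be on the analysis grid; no registration.
* Reported clinical-scale accuracy figures from the motivating study are
  not reproducible without its cohort and are deliberately not targets of
  this package's tests.

## A worked run

```{r, eval = FALSE}
co  <- generate_cohort(synthetic_cohort_spec())     # 30 HC + 30 AD, seed 42
run <- run_pipeline(co$volumes, co$gm, co$clinical, co$atlas)
print(run)
```

See the README for the output this prints and how to read it.
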