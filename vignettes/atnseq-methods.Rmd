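---
title: "Methods: monotone volume-decline evidence across ATN stages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: monotone volume-decline evidence across ATN stages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atnseq)
```

## The question and the model

The ATN classification binarizes three biomarker axes — amyloid (CSF
Aβ42/40, abnormal below the cutoff), tau (CSF phospho-tau181, abnormal
above), neurodegeneration (adjusted hippocampal volume abnormal below,
or CSF total tau abnormal above) — into 8 groups. If disease progresses
by a fixed order of biomarker conversions, regional gray-matter volume
should decline monotonically along that order. `atnseq` asks, for each
candidate ordering of four ATN groups, how well a *monotone-decline*
model explains an outcome, and ranks orderings by model evidence.

For outcome $y$ (an ROI volume or one voxel across subjects) and a
candidate sequence $s_1 \to s_2 \to s_3 \to s_4$ the model is

$$ y = X\beta + Z\gamma + \varepsilon, $$

where the mean-structure design $X$ codes $\beta_1$ as the mean of the
first group and $\beta_g$ ($g = 2,3,4$) as the successive difference
between groups $g$ and $g-1$ (column $g$ of $X$ is the indicator of
sequence position $\ge g$). Monotone decline is imposed by
$\beta_g \le 0$ for $g = 2,3,4$; the covariate coefficients $\gamma$
(age, sex, education, total intracranial volume, white-matter
hyperintensity load; mean-centered over the included subjects) are
unconstrained and are shared in the sense that every candidate sequence
model uses the same covariate columns. Candidate sequences are compared
with

$$ \mathrm{BIC} = n \ln(\mathrm{SSE}/n) + k \ln n , $$

the Gaussian-residual form; the minimal BIC wins.

### Assumptions

* Cross-sectional group ordering stands in for within-subject
  progression; nothing longitudinal is modelled.
* Residuals are homoskedastic Gaussian within each outcome; the BIC
  comparison is likelihood-based under that assumption.
* Covariate effects are linear and identical across groups.
* Within the 24-permutation comparison all models use the same subjects,
  so $n$ and $k$ are constant and BIC ranking is equivalent to SSE
  ranking (this is asserted in the test suite). In the 6-path comparison
  each path includes the subjects of its own four groups, so $n$ differs
  between models; the BIC values are then penalized per-model evidence
  on each path's own data, which is how the comparison is defined here
  (see Limitations).

## The constrained solver

The fit is a 3-inequality quadratic program small enough to solve
*exactly*: the solver enumerates all $2^3$ patterns of active
constraints ($\beta_g$ pinned to 0), solves each pattern by ordinary
least squares on the reduced design, discards infeasible solutions
(a free $\beta_g > 0$), and keeps the feasible minimum-SSE pattern. The
optimal active set's equality-constrained solution is the global
constrained optimum, so the enumeration is exact, deterministic and
trivially auditable. Patterns are visited unconstrained-first and a new
pattern must improve SSE by more than a $10^{-12}$ relative margin, so
ties resolve toward fewer active constraints. The test suite checks the
solver against two independent routes: a brute-force enumeration via
`lm.fit`, and `pracma::lsqlincon` (a quadratic-programming route); with
no covariates the fitted position means are verified to equal
pool-adjacent-violators (antitonic regression via `isoreg`) on the group
means.

`bic()` counts $k = 4$ mean-structure coefficients $+$ the number of
covariates $+ 1$ (residual variance) regardless of which constraints end
up active. Constant $k$ across sequences keeps the comparison
transparent; an `"effective"` mode that counts only inactive-constraint
coefficients is available for sensitivity analysis. A zero SSE (exact
fit, possible on noiseless or planted data) returns $-\infty$ with a
warning; several exact fits tie and the tie is broken by canonical
sequence order with the tie flag set (threshold $\Delta\mathrm{BIC} <
10^{-9}$).

## Sequence sets

* `permutation_sequences()`: all 24 orderings of the AD-continuum groups
  (A−T−N−, A+T−N−, A+T+N−, A+T+N+); the ACH ordering is the reference
  and is listed first, the 23 alternatives follow in lexicographic order
  as P01..P23. Aliases AP1 (A+T−N− → A+T+N− → A−T−N− → A+T+N+) and AP2
  (A+T−N− → A−T−N− → A+T+N− → A+T+N+) mark the two transient-increase
  permutations of particular interest.
* `conversion_paths()`: the 6 ways to convert from A−T−N− to A+T+N+
  flipping one category per step, named by conversion order (ACH/ATN,
  ANT, TAN, TNA, NAT, NTA).

Group labels use ASCII hyphens internally (`"A-T-N-"`) to avoid
Unicode-minus pitfalls in files and command lines; `pretty_label()`
renders true minus signs for display.

## Classification machinery

**Cutoffs.** Defaults are the published fixed values (A = 0.09 ratio,
T = 57 pg/ml, N = 2821.1 µl adjusted hippocampal volume or 470 pg/ml
total tau). Equality at a cutoff is classified normal in every category:
no strict-inequality convention is forced by the definitions, one had to
be chosen, and a unit test pins it so the alternative is a one-line
change. Each cutoff may instead be estimated: `"gmm"` fits a
two-component Gaussian mixture and returns the equal-posterior point
between the component means; `"youden"` maximizes sensitivity +
specificity − 1 against the clinical diagnosis (impaired MCI/DAT versus
unimpaired NC/SCD) over midpoint candidates, breaking ties toward
higher specificity.

**Mixture fitting.** `estimate_gmm_cutoff()` delegates the EM fit to
`mclust` (G = 2, unequal variances), whose model-based hierarchical
initialization is deterministic — the `seed` argument is honoured for
reproducibility of any randomized path but does not change results on
ordinary data. Two degeneracy guards protect the cutoff: component
means closer than half the pooled component SD, and a fitted mixture
whose density has no dip between the means. The second guard matters in
practice: EM happily splits a *unimodal* Gaussian sample into two
heavily overlapping components about one pooled SD apart, which the
separation rule alone would accept; requiring an actual density dip
between the means rejects such fits as degenerate, and the caller can
fall back to a fixed cutoff.

**Volume adjustment.** `adjust_volume()` residualizes hippocampal volume
on the covariates and re-centers at the grand mean of the raw volumes,
so adjusted values stay in µl. The model is fit on all subjects with
complete data by default — the single-regression reading of the
procedure — with a config flag (`adjust_on = "atn_negative"`) to
restrict the fit to biomarker-negative subjects instead. Whether the
mixture dichotomization of hippocampal volume should see raw or adjusted
values is genuinely ambiguous; both are supported and the default is
adjusted values, with the published fixed cutoff available as the
fixed-cutoff alternative. Adjustment is idempotent (residuals are
orthogonal to the covariates), which the tests assert.

## Maps, trend test and FDR

`voxelwise_compare()` applies the sequence comparison independently at
every voxel inside the gray-matter mask (voxels whose subject-mean value
reaches the absolute threshold, default 0.05). Because the candidate
designs depend only on the group labels — not on the voxel outcome — the
per-pattern QR factorizations are shared across voxels and the
comparison vectorizes; the tests verify the vectorized path equals the
per-voxel path exactly. Maps are analyzed within the mask and written
with out-of-mask voxels set to 0 plus a companion mask image.

The ROI tables report a one-sided decline trend: OLS with the sequence
position (1..4, centered) as a linear regressor plus covariates,
$t = \hat\beta_{\mathrm{pos}} / \mathrm{SE}$, one-sided $p$ for a
negative slope. This is this package's operationalization of an ROI
effect-size statistic — the source analyses do not define theirs
precisely, so numerical equivalence with published $T$ or "log p" values
is *not* claimed; the package reports $-\log_{10} p$. Voxel-wise maps
apply Benjamini–Hochberg FDR across in-mask voxels per tested sequence
(not pooled across sequences), with q-values from the standard monotone
transform; the step-up flags are checked against an independent
reference implementation on random p-vectors.

## The synthetic-data generator

`simulation_spec()` defaults emulate the DELCODE baseline sample as
summarized in `delcode_reference()`:

* the 8 group sizes (143, 41, 29, 14, 45, 23, 61, 81; total 437),
  assigned by fixed-size sampling so realized sizes are exact;
* bimodal marker components placed at the printed normal/abnormal group
  means and SDs (e.g. Aβ42/40 `N(0.110, 0.012²)` vs `N(0.060, 0.013²)`;
  hippocampal volume `N(3140, 210²)` vs `N(2600, 180²)` µl);
* a 0.7 within-component correlation between phospho- and total tau,
  which keeps tau-discordant groups rare, as observed;
* covariates typical of an elderly memory-clinic cohort (age ≈ 69.5 ±
  5.5 y rising ~1.2 y per abnormal marker, 48 % female, education
  14.3 ± 2.9 y, TICV 1400 ± 120 ml, log-normal WMH), with hippocampal
  volume confounded by age (−10 µl/y), sex, TICV and WMH so that
  covariate adjustment is non-trivially exercised;
* a 24×24×24 voxel grid at 2 mm with two planted axis-aligned box
  regions — one monotone-decline region along the ACH ordering (offsets
  0, −1, −2, −3 residual SDs) and one biphasic region (0, +1, 0, −2;
  rise at amyloid conversion, minimum at full pathology) — against null
  background, Gaussian noise, and optional Gaussian smoothing (off by
  default; 6 mm FWHM mirrors common VBM pipelines).

Everything is a pure function of the spec (seeded; the voxel draw uses
spec seed + 1 so cohort and images are jointly reproducible). The
generator emulates the *statistical* structure the analysis assumes —
bimodal markers, linear confounding, box-shaped effects, independent
Gaussian voxel noise. It does not emulate anatomy, atlas-shaped regions,
spatially correlated noise beyond optional smoothing, scanner/site
effects, or longitudinal change; passing tests therefore demonstrate
correctness of the machinery under the assumed model, not validity of
the scientific conclusion on real images.

Smoothing uses a separable truncated Gaussian (radius 4σ) with
row-renormalization, so constant images pass through unchanged and total
mass is preserved to truncation accuracy (~10⁻⁴ at 4σ).

## Numerical choices

* Masks read from images binarize at > 0.5 (the common
  probabilistic-mask convention); grid congruence requires identical
  shape and voxel sizes equal within 10⁻⁴ mm.
* Each sequence position must contain at least 3 subjects
  (`min_group_n`); sequences failing this on a given cohort are dropped
  from the comparison with a warning.
* Missing biomarkers exclude a subject from classification with a
  logged count — never imputed.
* Hippocampal volume is handled in µl internally; `hv_units = "ml"`
  converts on read.
* Output maps default to 32-bit float NIfTI.
* Constraint feasibility tolerance 10⁻¹⁰; oracle agreement tolerance in
  tests 10⁻⁸.

## Problem sizes in the test suite

The suite exercises the solver on hundreds of random instances with
n ≤ 60 and 5 covariates; calibration uses 2000 null trend simulations
and 1000 random FDR vectors; recovery experiments use 10×10×10 grids
with 20 subjects per group over 10 seeds. These sizes were chosen to
make the statistical assertions sharp while keeping the default test run
in the tens of seconds; all scale linearly if larger checks are wanted.

## Limitations

* Inference after constrained estimation is not order-restricted
  (no chi-bar-square); the trend test is an unconstrained contrast.
* BIC across the 6 conversion paths compares models fitted on different
  subject subsets (each path's own four groups); treat those evidence
  differences as descriptive.
* The cutoff machinery estimates one marker at a time; no joint
  multivariate classification.
* Winner maps are voxel-wise; no cluster-extent or spatial inference.
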