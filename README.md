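# atnseq

Model evidence for monotone gray-matter decline across ATN biomarker
stages.

## The problem

The ATN scheme classifies participants in an aging/dementia cohort on
three binary biomarker axes — **A**myloid (CSF Aβ42/40 ratio, abnormal
low), **T**au (CSF phospho-tau181, abnormal high) and
**N**eurodegeneration (covariate-adjusted hippocampal volume, abnormal
low, or CSF total tau, abnormal high) — yielding 8 groups from A−T−N− to
A+T+N+. The amyloid cascade hypothesis (ACH) predicts a fixed conversion
order, A−T−N− → A+T−N− → A+T+N− → A+T+N+, and hence a *monotone decline*
of regional gray-matter volume along that ordering.

`atnseq` turns that prediction into a testable model-selection problem.
For an outcome *y* (an ROI volume, or every voxel of a modulated-GM
stack) and a candidate ordering of four ATN groups, it fits

  y = Xβ + ε,  subject to β₂, β₃, β₄ ≤ 0,

where β₁ is the mean of the first group and β_g (g = 2, 3, 4) the
successive difference between adjacent groups; the inequality
constraints encode monotone decline, and covariates (age, sex,
education, TICV, WMH) enter unconstrained. Candidate orderings — all 24
permutations of the AD-continuum groups, or the 6 three-step conversion
paths from no pathology to full pathology (ACH/ATN, ANT, TAN, TNA, NAT,
NTA) — are compared by

  BIC = n·ln(SSE/n) + k·ln(n),

with minimal BIC winning. The constrained fit is solved exactly by
enumerating the 2³ active-constraint patterns. Outputs include
voxel-wise winner maps, winner percentages, FDR-corrected one-sided
trend maps (−log10 p), ROI summaries and Braak-stage composites. A
seeded synthetic-data generator emulates the cohort structure of the
DELCODE baseline sample (bimodal markers, covariate confounding,
planted monotone / biphasic / null regions) so the whole pipeline is
testable with known ground truth.

## Worked example

```r
library(atnseq)

spec <- simulation_spec(seed = 1)       # DELCODE-like defaults, 437 subjects
sim  <- simulate_cohort(spec)
res  <- assign_groups(sim$cohort)       # fixed published cutoffs by default
res
#> ATN classification of 437 subjects ( 0 excluded for missing markers)
#> A−T−N− A−T−N+ A−T+N− A−T+N+ A+T−N− A+T−N+ A+T+N− A+T+N+
#>    133     38     33     10     63     34     62     64
res$cutoffs
#> ATN cutoffs [fixed]: A < 0.09, T > 57, N < 2821.1 ul (aHV)

vox <- simulate_voxels(sim, spec)       # 24x24x24 grid, planted regions
ev  <- voxelwise_compare(vox$dataset, sim$cohort,
                         permutation_sequences(), groups = res)
round(sort(winner_percentages(ev), decreasing = TRUE)[1:5], 2)
#>  ACH  P06  P18  P22  P13
#> 8.49 8.41 4.82 4.72 4.66

roi <- roi_mask("planted_monotone", vox$truth$region_id == 1)
roi_summary(vox$dataset, sim$cohort, roi, permutation_sequences(),
            groups = res, evidence = ev)
#>                roi best_sequence   t         p reference_rank ref_vx_pct
#> 1 planted_monotone           ACH -40 9.59e-126              1       99.9
```

The winner percentages answer "in what share of gray matter is each
conversion ordering the best monotone explanation?": here the ACH
ordering wins most voxels, driven by the planted monotone region
(99.9 % ACH, reference rank 1 of 24, strongly negative decline trend),
while the planted biphasic region is claimed by the reordered
permutation P06 (alias AP2), which places the all-negative group *after*
amyloid conversion — the signature of a transient volume increase at
A conversion.

A thin CLI with `simulate`, `classify`, `fit-roi`, `fit-voxels` and
`summarize` subcommands is installed at `inst/cli/atnseq.R`.

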