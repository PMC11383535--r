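---
title: "Item-wise RSA of memory encoding and retrieval: models and methods"
author: "memrsa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Item-wise RSA of memory encoding and retrieval: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

When people study pictures of everyday objects and later recognize their
names, the cortical location of the strongest stimulus representations
shifts: occipito-temporal cortex (OTC) dominates during encoding, lateral
inferior parietal cortex (IPC) during retrieval. Two questions follow. Does
this shift reflect a change in representational *content* — from
visual/concrete to semantic/abstract — or only in *location*? And do the
shifting representations actually support memory, rather than merely
reflecting task differences between the two phases?

`memrsa` implements an item-wise representational similarity analysis (RSA)
pipeline built to answer such questions, together with a synthetic-study
generator that plants known effects so that every stage can be validated
against ground truth.

# The core statistic: the item-wise RSM-activity fit (IRAF)

Classical model-based RSA correlates an entire model representational
similarity matrix (RSM) with an entire activity-pattern matrix (APM),
yielding one number per region. The IRAF instead correlates, for each item
$i$, the $i$-th row of the APM (that item's pattern similarity to every
other item) with the $i$-th row of the model RSM, excluding the
self-similarity element:

$$\mathrm{IRAF}_i \;=\; \mathrm{cor}\big(\mathbf{A}_{i,-i},\, \mathbf{R}_{i,-i}\big).$$

This preserves trial-level variance, so stimuli can enter group models as a
crossed random effect alongside participants, and memory success can be
modeled per trial instead of as a uniform condition. `compute_iraf()`
implements the statistic; `build_iraf_table()` assembles the long-format
analysis table over participants, regions, phases, feature types and items.
Raw Pearson $r$ is the default; a Fisher-$z$ option (`fisher_z = TRUE`)
applies $\operatorname{atanh}$, a strictly monotone transform, for users who
prefer variance-stabilized values.

## Inputs to the statistic

**Model RSMs** (`build_model_rsm()`). Feature norms — a nonnegative
concept-by-feature matrix of normalized report frequencies with each feature
labeled *visual* or *semantic* — yield one RSM per category: cell $(i,j)$ is
the Pearson correlation of the two concepts' category-restricted feature
vectors. `compare_rsms()` quantifies the visual–semantic overlap with a
Spearman $\rho$ over the vectorized strict lower triangle (rank correlation
for matrix-level comparison, Pearson for feature and voxel vectors), plus an
item-wise $\rho$ per row. `residualize_rsms()` removes the shared variance by
mutual OLS regression of the vectorized triangles; for standardized vectors
with correlation $r$ the two residual vectors have correlation exactly $-r$,
which is why residualized models of partially overlapping feature spaces are
anticorrelated by construction. Whole-matrix residualization is the default;
a `per_row` variant is provided because the granularity at which published
residual models were computed is not generally stated.

**Single-trial betas** (`double_gamma_hrf()`, `build_design()`,
`estimate_betas()`). Trial-wise activation patterns come from a single
simultaneous least-squares GLM: one regressor per trial (impulse at onset
convolved with the canonical double-gamma HRF — 6 s peak, 16 s undershoot,
unit dispersions, peak:undershoot ratio 6, all configurable), plus supplied
nuisance regressors and an intercept. Rank deficiency raises an error rather
than silently pseudo-inverting. Preprocessing (slice timing, motion, high-pass
filtering, normalization) is out of scope; nuisance columns are accepted as
given.

**APMs with temporal correction** (`build_apm()`, `build_time_rsm()`,
`regress_time()`). The APM is the Pearson correlation matrix of the valid
trials' voxel patterns. Because nearby trials share scanner noise, a
temporal-proximity RSM is built — within a run, $1 - |t_i - t_j| / D_{run}$
with $D_{run}$ the largest within-run onset distance; 0 across runs (runs do
not share drift) — and regressed out of the APM's lower triangle (OLS with
intercept, residuals re-folded symmetric). The intercept is not re-added:
IRAF uses correlations, which are shift invariant. If the temporal RSM is
constant there is nothing to regress and the APM is mean-centered with a
warning.

**Trial exclusions** (`filter_trials()`). Catch trials are always excluded.
A "don't know"/wrong-letter press at encoding marks the item as unnamed, so
both its encoding and retrieval trials are excluded.

# Behavioral labels and the false-alarm-tendency adjustment

Recognition responses are 4-point confidence judgments (1 = definitely new
… 4 = definitely old); 3–4 collapse to "old". A participant's *false-alarm
tendency* is their mean response to new items; a one-sample $t$ test against
2 ("probably new") flags participants whose mean exceeds 2 at two-sided
$p < .05$ (`false_alarm_tendency()`). Two-sided $p$ values are used because
published per-participant tables report small $p$ for negative $t$ as well,
which a one-sided greater-than test cannot produce; flagging additionally
requires the mean to exceed 2. For flagged participants "probably old" hits
are demoted to forgotten (`adjust_memory_labels()`); "definitely old" is
never demoted, so the adjustment is monotone. Valid-trial counts are fixed
by the exclusion rules and unaffected by demotion. `summarize_hit_rates()`
reports adjusted hits / valid trials per participant with the group mean and
SE. The package bundles a published-scale 19-participant count table
(`example_behavior_counts()`) whose group summary (mean .62, SE .03) and
per-participant $t$ values reproduce from its printed means and SEs.

# Inference: crossed random-intercept mixed models

Per region, IRAF values enter a three-factor model — memory success ×
memory phase × representation type, full factorial — with random intercepts
for participant and stimulus, fitted by REML (`fit_lmm()`, on lme4 /
lmerTest). Fixed factors use sum-to-zero contrasts because Type III sums of
squares are contrast-dependent and this is the convention under which they
correspond to marginal tests. `type3_anova()` returns $F$ tests with
Satterthwaite denominator degrees of freedom; $p$ values are corrected with
the Benjamini–Hochberg step-up rule in a single family spanning all regions
and terms (`fdr_adjust()`). Models that genuinely fail to converge are
flagged and excluded downstream with a log entry — a boundary ("singular")
fit is not a failure, merely a variance component estimated at zero.
`posthoc_means()` computes marginal-mean remembered − forgotten contrasts
within each phase (emmeans, Satterthwaite df).

## Sorting interaction patterns

Regions with a phase × success interaction fall into two qualitative
patterns: *retrieval success* (success effect at retrieval, none at
encoding) and *encoding–retrieval flip* (success at retrieval, reversed —
forgotten > remembered — at encoding). The boundary is genuinely ambiguous:
published pattern tables show negative encoding contrasts in both groups.
`classify_flip_pattern()` therefore exposes the rule as configuration. Both
patterns require a positive significant retrieval contrast; the default rule
(`negative_estimate`) calls any negative encoding estimate a flip, while
`significant_negative` requires the encoding contrast itself to be
significantly negative. The planted-pattern analyses in this package use
`significant_negative`, because a retrieval-only region has a null encoding
contrast whose estimate sign is a coin flip — under the `negative_estimate`
rule half of all genuinely retrieval-only regions would be labeled flips.

## The phase × area model

`fit_area_model()` tests whether the encoding–retrieval difference depends
on area (OTC vs IPC) using remembered trials only, with random intercepts
for feature type, participant, stimulus and region. A 2-level grouping
factor (feature type) as a random intercept is statistically unusual; it is
implemented as specified with a switch (`feature_type_random = FALSE`) to
move feature type to the fixed part.

## Power by simulation

`power_sim()` simulates the crossed design — by default 19 participants ×
300 items × 2 phases × 2 feature types, participant and item intercept SDs
of 0.1 in residual-SD units (values not derivable from published reports;
configurable), unit residual — plants a condition effect of $d$ residual
SDs, fits the mixed model and tests the effect at $\alpha$. At $d = 0.4$,
$\alpha = .05$ this design yields power indistinguishable from 1, well
above the 85% planning bound; at $d = 0$ the rejection rate equals the
nominal level, a size check included in the test suite.

# Cross-phase decoding of feature type

To show that visual and semantic IRAFs are distinguishable even when mean
effects of representation type are absent, `train_transfer()` fits a linear
soft-margin SVM (fixed $C = 1$) to encoding-phase IRAF samples — one scalar
sample per item and feature type, the minimal reading of a per-region
feature-type classifier — and evaluates it on retrieval-phase samples only.
Chance is calibrated empirically: `simulate_null()` runs the identical
pipeline on label-free simulated participants, and `chance_test()` compares
pooled correct/incorrect counts against the null proportion with a 1-df
chi-squared statistic. The raw null draws are returned so an
empirical-quantile test can be substituted.

# The synthetic-study generator

`gen_study()` produces trial tables, graded responses, and per-region
single-trial voxel patterns with known planted effects. Its components:

- **Feature norms** (`gen_feature_norms()`): rectified-Gaussian values,
  column-normalized; the semantic block is a convex mixture (weight
  `cross_corr`) of duplicated visual features and fresh ones, so the
  visual–semantic RSM correlation rises monotonically from ≈ 0 to exactly 1.
  Every feature is nonzero for at least two concepts, mirroring norming
  practice.
- **Patterns**: per region, fixed voxel loading maps $V, S$ (i.i.d. standard
  normal, drawn once) project the item's visual and semantic feature vectors;
  the trial pattern is $w_v V f_v + w_s S f_s + \sigma \varepsilon$ with
  weights depending on region class, phase and the trial's memory outcome.
  Random projection approximately preserves the feature-space similarity
  structure, so planted weights translate into IRAF differences.
- **Behavior**: a latent per-item strength $\theta \sim N(0.85, 1)$ shared
  across participants (inducing an item random effect) plus participant
  response noise (SD 0.5) is binned at thresholds $(-0.25, 0.5, 1.25)$ into
  the 4-point response. An old item is remembered when its response is ≥ 3,
  and the same outcome drives the planted pattern weights — behavioral
  labels and neural planting are consistent by construction. The defaults
  give an adjusted hit rate near .62 and an unbiased mean new-item response
  near 1.8, typical of a day-delayed conceptual recognition test; a positive
  `bias` produces flaggable old-biased participants.
- **BOLD** (`gen_bold()`): optional forward model — true betas times
  HRF-convolved impulses plus i.i.d. Gaussian noise — used to round-trip the
  GLM. No distributional claim about real scanner noise is intended; motion,
  physiology and drift are not simulated (drift-like structure for testing
  the temporal correction is planted directly at the pattern level in the
  test suite).

The reference configuration (`default_planted_effects()`) encodes the
qualitative target pattern: OTC-like regions stronger at encoding than
retrieval regardless of outcome; IPC-like regions with a success effect at
retrieval only; and a flip region (forgotten > remembered at encoding,
remembered > forgotten at retrieval).

What passing tests on this generator do **not** show: real fMRI noise is
neither Gaussian nor i.i.d., real feature norms are sparse counts rather
than rectified Gaussians, and real memory outcomes are not perfectly coupled
to a unidimensional latent strength. The generator validates the *pipeline's
logic* — sign conventions, exclusion rules, model specification, error
control — not the physiological realism of any effect size.

# Numerical and scale choices

- Vectorization uses the strict lower triangle; symmetric matrices would
  otherwise double-count cells.
- Item-wise vectors exclude the self element (diagonal is 1 in models,
  residual-corrected in APMs; it carries no information and breaks scaling).
  Whether within-run cell pairs should additionally be excluded after the
  time regression is not settled; all off-self cells are retained here.
- Degenerate rows (constant pattern vectors) yield `NA` IRAFs that are
  dropped with a reported count, never imputed.
- Simulation sizes: the planted-pattern recovery analysis runs at 12
  participants × 60 old items × 3 regions × 24 voxels, fixed by a pilot
  power analysis of the hardest component (the flip region's encoding
  contrast, mean $|t| \approx 5$ at this size); the Type III size check uses
  the model-level global null (participant and item intercepts active, all
  fixed effects zero) at 10 participants × 20 items with 500 replicates; the
  power analysis uses the full 19 × 300 × 2 × 2 design.
- All generators are pure functions of their arguments and a seed; rerunning
  any pipeline configuration reproduces byte-identical outputs.

# Known limitations

- ROI-wise analysis only; no searchlight variant.
- No slice-timing/motion correction, normalization or filtering — the GLM
  expects preprocessed (or synthetic) runs and treats nuisance regressors as
  given.
- No Kenward–Roger degrees of freedom, random slopes, or Bayesian fitting;
  random intercepts only, as in the target analyses.
- The chi-squared chance test is one defensible reading of "summed
  accuracies compared with simulated participants"; the null draws are
  exposed for alternative tests.
- Encoding–retrieval similarity (correlating a stimulus's encoding pattern
  with its own retrieval pattern) is deliberately not implemented; the
  package contrasts representational strength across phases instead.
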