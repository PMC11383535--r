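# memrsa

Item-wise representational similarity analysis (RSA) of memory encoding and
retrieval.

## The problem this package addresses

fMRI studies of episodic memory repeatedly find that the strongest stimulus
representations sit in occipito-temporal cortex (OTC) while people encode
pictures, but in lateral inferior parietal cortex (IPC) while they retrieve
them — a *representational encoding–retrieval shift*. Whether that shift
reflects a change in representational content (visual → semantic) or only in
location, and whether it actually supports memory, requires an analysis that
(a) separates visual from semantic stimulus models and (b) indexes
representational strength *per item*, so that remembered and forgotten
trials can be compared within the same region and phase.

`memrsa` is a tested R implementation of that analysis for cognitive
neuroscientists: from feature norms and single-trial voxel patterns (real
NIfTI volumes or a built-in synthetic generator with planted ground truth)
through the item-wise statistic, behavioral bias adjustment, mixed-effects
inference, cross-phase decoding, and simulation-based power analysis.

## The core statistic

For item *i*, region *r*, and phase *p*, the **item-wise RSM-activity fit
(IRAF)** is

```
IRAF(i) = cor( APM[i, -i], RSM[i, -i] )
```

the Pearson correlation between row *i* of the region's activity-pattern
matrix (APM; pairwise pattern correlations of the valid trials, with
temporal proximity regressed out) and row *i* of a model representational
similarity matrix (RSM; pairwise correlations of normative visual or
semantic feature vectors), excluding the self-similarity element. IRAFs
retain trial-level variance, so they enter crossed random-intercept mixed
models (participant and stimulus) with fixed effects of memory success ×
memory phase × representation type, Type III F tests with Satterthwaite
degrees of freedom, and Benjamini–Hochberg FDR correction across regions
and terms.

## Worked example

Simulate a study whose ground truth contains the three signature effects —
an OTC-like region stronger at encoding, an IPC-like region with a
memory-success effect only at retrieval, and a region with an
encoding–retrieval "flip" — then run the full pipeline:

```r
library(memrsa)

design <- study_design(n_participants = 12, n_old = 60, n_catch = 8, n_new = 16,
                       roi_spec = data.frame(
                         roi_id    = c("otc1", "ipc1", "flip1"),
                         roi_class = c("OTC-like", "IPC-like", "other"),
                         n_voxels  = 24))
norms <- gen_feature_norms(n_concepts = 84, n_visual = 30, n_semantic = 30,
                           cross_corr = 0.25, seed = 1)
study <- gen_study(design, default_planted_effects(), norms, seed = 1)

front <- study_iraf_table(study)   # exclusions, bias adjustment, APMs, IRAFs
head(front$iraf, 3)
#>   participant roi_id roi_class    phase feature_type item  iraf     memory
#> 1         p01   otc1  OTC-like encoding       visual c082 0.259 remembered
#> 2         p01   otc1  OTC-like encoding       visual c058 0.259 remembered
#> 3         p01   otc1  OTC-like encoding       visual c042 0.144 remembered

summarize_hit_rates(hit_counts(front$trials))
#> <hit_summary> 12 participants: mean adjusted hit rate 0.653 (SE 0.017)

fits <- roi_effects(front$iraf, flip_rule = "significant_negative")
subset(fits$effects, effect %in% c("phase", "memory:phase") & q < 0.05,
       select = c(roi_id, effect, F, df_den, q))
#>    roi_id       effect     F df_den        q
#> 2    otc1        phase 394.6   2554 1.92e-80
#> 9    ipc1        phase  29.6   2554 2.02e-07
#> 11   ipc1 memory:phase  31.9   2554 9.61e-08
#> 16  flip1        phase  22.7   2554 5.87e-06
#> 18  flip1 memory:phase  52.7   2554 5.34e-12

fits$posthoc[, c("roi_id", "phase", "estimate", "t", "p")]
#>   roi_id     phase estimate      t        p
#> 1   otc1  encoding -0.01006 -1.050 2.94e-01
#> 2   otc1 retrieval  0.00417  0.435 6.63e-01
#> 3   ipc1  encoding  0.00460  0.484 6.29e-01
#> 4   ipc1 retrieval  0.06741  7.091 1.71e-12
#> 5  flip1  encoding -0.02546 -2.678 7.46e-03
#> 6  flip1 retrieval  0.05579  5.868 4.98e-09

fits$patterns
#>   roi_id                 pattern
#> 1   otc1                    none
#> 2   ipc1       retrieval_success
#> 3  flip1 encoding_retrieval_flip
```

Reading the output: the OTC-like region shows a massive phase main effect
(stronger encoding representations) but no success contrast in either phase;
the IPC-like region's remembered − forgotten contrast is significant at
retrieval only (*t* = 7.09) — the retrieval-success pattern; and the flip
region couples that retrieval success with a significantly *negative*
encoding contrast (*t* = −2.68): stronger encoding representations predicted
forgetting. Exactly the planted truth.

Power for the full-scale design:

```r
power_sim(d = 0.4, n_participants = 19, n_items = 300, reps = 50, seed = 1)
#> <power_estimate> d = 0.40, alpha = 0.050: power 1.000 (MC SE 0.000, 50 reps)
```

A single call, `run_pipeline(config, out_dir)`, executes every stage and
writes the trial table, IRAF table, behavioral report, per-region effect and
post hoc tables, pattern labels and a JSON manifest (seed, configuration,
row counts, non-converged models).

See the methods vignette (`vignettes/memrsa-methods.Rmd`) for the models,
their assumptions, tunable parameters, and the synthetic generator's scope.

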