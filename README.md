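# dfcsubtype

Unsupervised subtype discovery for resting-state fMRI cohorts, built
around individual-level *normative deviations* of dynamic
functional-connectivity features. The intended users are imaging
researchers stratifying patient groups (here modelled on first-episode,
drug-naive depression) whose raw data are sampled as per-subject regional
BOLD time series (time x ROI tables) plus a subject manifest.

## The method

For each subject with time series over m ROIs (TR = 2 s, >= 210 volumes):

1. **Sliding-window dFC** — Pearson correlations in 60 s windows stepped
   by one volume, Fisher-z transformed, vectorized over the
   E = m(m-1)/2 edges: a W x E matrix per subject.
2. **Guided ICA** — group-level edge-space components (PCA to K = 20, then
   fixed-point logcosh ICA) from an independent healthy cohort; each
   analysis subject's components are back-reconstructed by a one-unit
   negentropy fixed point anchored to its group reference, with
   time-varying weights from per-window OLS.
3. **40 features** — per component, the weighted-graph global efficiency
   of its loading pattern and the fluctuation coefficient (mean |Δ|) of
   its weight trajectory.
4. **Normative z-scores** — per feature, degree-2 polynomial quantile
   curves over age (5th/50th/95th percentile, pinball loss) fitted on
   matched healthy controls with a 10-fold ensemble; each patient scores

   `z = (C_real − C_50th(age)) / (C_95th(age) − C_5th(age))`,

   averaged over folds.
5. **Subtyping** — wrapper forward selection with k-means over 100
   subsampled runs (informative features: selection frequency > 0.8),
   then 100 repeated k-means runs; each patient gets its modal label and
   a certainty `max_i n_i / n` (subjects under 0.6 flagged), with mean
   silhouette, center instability and mean stability as diagnostics.
   Freedman–Lane permutation tests (n = 5000, age/sex/education
   covariates, p < .01) contrast deviations between controls and
   subtypes.

Because real cohorts of this kind are access-restricted, the package
includes a fully specified synthetic cohort generator
(`generate_ground_truth()` / `generate_cohort()`) with planted components,
age trends and deviation subtypes, used by the test suite to validate
every stage against ground truth.

## Worked example

Simulate a cohort at reduced desk scale (m = 30 ROIs, 91 patients with
two planted subtypes, 91 base controls, 60 ICA-guidance controls) and run
the full pipeline:

```r
library(dfcsubtype)

truth  <- generate_ground_truth(K_true = 20, m = 30, sparsity = 0.1, seed = 42)
cohort <- generate_cohort(truth, n_patients = 91, n_controls_base = 91,
                          n_controls_ica = 60, T_volumes = 210, tr = 2,
                          seed = 42)
res <- run_full_pipeline(cohort$manifest, cohort$series,
                         pipeline_config(n_permutations = 1000, seed = 42))
print(res)
#> <dfc_pipeline_result>
#>   91 patients, 91 matched controls, K = 20, 40 features
#>   informative features (3): fc_IC02, fc_IC04, fc_IC06
#> <cluster_ensemble> k = 2, 100 runs: sizes 15/76; silhouette 0.763,
#>   instability 0.000, stability 1.000
```

The clustering recovers the planted 16%/84% subtype split exactly
(15 vs 76 patients; every subject's certainty is 1.0):

```r
lab <- tidy(res)   # subject_id, final_label, certainty, retained
planted <- cohort$truth$subtype_labels[lab$subject_id]
adjusted_rand_index(lab$final_label[lab$retained], planted[lab$retained])
#> [1] 1
```

`silhouette 0.763` says the two subtypes are well separated on the
informative deviation features; `stability 1.000` says all 100 clustering
runs agreed for every retained subject. The permutation contrasts show
where the subtypes differ — here subtype I carries broadly elevated
fluctuation deviations:

```r
dplyr::filter(res$stats, significant, contrast == "subtype1_vs_subtype2")
#> # A tibble: 20 x 6
#>    feature     t   p_perm direction significant contrast
#>  1 fc_IC01 -14.5 0.000999        -1 TRUE        subtype1_vs_subtype2
#>  2 fc_IC02 -19.7 0.000999        -1 TRUE        subtype1_vs_subtype2
#>  ...
```

Each fitted object has `tidy()` / `glance()` methods and an `autoplot()`
(selection frequencies, cluster scatter, normative curves, permutation
results).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates a synthetic cohort from the given seed, runs every pipeline
stage end-to-end (QC, matching, dFC, group and guided ICA, features,
normative deviations, selection, repeated clustering, permutation
contrasts), logs the recovered-subtype agreement and clustering
diagnostics, and writes the acceptance report to `--out`.
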