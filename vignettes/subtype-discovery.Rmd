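---
title: "Subtype discovery from dynamic functional connectivity: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subtype discovery from dynamic functional connectivity: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dfcsubtype)
```

# The scientific problem

Major depressive disorder is biologically heterogeneous: patients meeting
the same diagnostic criteria can carry different patterns of functional
brain-network alteration. `dfcsubtype` implements an individual-level
stratification pipeline for resting-state fMRI cohorts of first-episode,
drug-naive patients: instead of testing for case--control differences at
the group level, it quantifies how far each patient's brain-network
features deviate from an age-referenced healthy norm, and clusters patients
on those deviations.

The pipeline has five stages:

1. **Dynamic functional connectivity (dFC).** Per subject, Pearson
   correlations among m regional BOLD time series are computed in sliding
   windows (default 60 s windows stepped by one repetition time),
   Fisher-z-transformed, and vectorized over the E = m(m-1)/2 edges.
2. **Reference-guided ICA.** Group-level independent components are
   estimated from an independent healthy "ICA-guidance" cohort by PCA
   reduction to K components (default 20) followed by fixed-point logcosh
   ICA in edge space. Each analysis subject's components are then
   back-reconstructed with the group components as anchors: a one-unit
   negentropy fixed point on the subject's whitened dFC whose every update
   is blended toward the reference direction, together with per-window OLS
   weights that describe each component's time-varying expression.
3. **Network features.** Each subject is summarised by 2K scalars: the
   weighted-graph global efficiency of each component's loading pattern
   (max-normalized absolute loadings; edge length = 1/weight) and the
   fluctuation coefficient of each component's weight trajectory (mean
   absolute frame-wise change).
4. **Normative deviations.** On the matched healthy controls, each
   feature's age dependence is modelled by degree-2 polynomial quantile
   curves at the 5th/50th/95th percentiles (pinball-loss minimization).
   A patient's deviation is `z = (c - q50(age)) / (q95(age) - q5(age))`,
   averaged over a 10-fold cross-validated ensemble of curve sets.
5. **Subtyping.** Wrapper forward selection with k-means identifies the
   informative deviation features across 100 subsampled runs (frequency
   > 0.8); 100 repeated k-means runs on the informative features give each
   patient a modal label with a certainty value (`max_i n_i / n`);
   subjects below the certainty threshold (default 0.6) are flagged.
   Covariate-adjusted permutation tests (Freedman--Lane; age, sex and
   education as nuisance covariates) then contrast feature deviations
   between controls and subtypes.

# The synthetic cohort: a stated world

Real data of this kind are access-restricted, so the package ships a fully
specified generator with ground truth at every stage. Its defaults are the
conditions the pipeline is validated under, chosen once and documented
here.

**Latent structure.** K_true sparse symmetric edge patterns C_k (default
sparsity 0.1) with loadings drawn from ±U(0.18, 0.33)/sqrt(K_true). The
1/sqrt(K) scaling keeps the time-varying covariance
Sigma(t) = I + sum_k w_k(t) A_k positive definite at any model order — the
spectral radius of a sum of K independent sparse random symmetric matrices
grows like sqrt(K) — so the eigenvalue repair (clipping at 1e-6) stays a
rare safeguard rather than a distortion. Patterns are redrawn until all
pairwise cosines are below 0.3, keeping recovery well-posed.

**Two feature channels.** Each component carries two subject-level
parameters:

* a *structure* parameter delta, which adds a sparse "densifier" pattern
  D_k (twice the support, same amplitude range) to the component:
  A_ik = C_k + delta_ik D_k. Extra edges raise the pattern's global
  efficiency, so delta drives the `ge` features;
* a *fluctuation scale* s, which multiplies the amplitude of the
  component's weight trajectory and drives the `fc` features.

Both parameters follow quadratic age trends (centred at 34 years) plus
between-subject Gaussian noise (SD 0.08 and 0.10).

**Weight trajectories** are smoothed Gaussian random walks (moving-average
width = the 30-volume carrier period), standardized, and
*fluctuation-calibrated*: each trajectory is rescaled so that the mean
absolute first difference of its running 30-volume means is exactly 0.02.
This makes the fluctuation coefficient of the windowed weights an exact
linear function of s, removing realization noise from the fc channel.

**Signal carrier.** BOLD-like series are x_t = L(t) z_t + noise_sd * e_t
with L(t)L(t)' = Sigma(t). The carrier z is a periodic, exactly whitened
block of `carrier_period` (default 30) volumes: every 30-volume window
contains one full period, so sliding-window covariance estimates carry *no
carrier sampling noise*. In the noiseless limit (noise_sd = 0, constant
weights, m < period) every window correlation equals the analytic
correlation of Sigma exactly — a property the tests exploit. For
m >= period the block is a constant rank-(period-1) projection per
subject; window estimates are still noiseless but the carrier is low-rank
(a documented departure from full-rank BOLD noise). `noise_sd` (default
0.02 on unit-variance signals) is therefore the only stochastic term in
the window estimates; the default is set so that the generator's stated
recoverability properties (planted patterns recovered at |r| >= 0.9,
planted subtypes separable end-to-end) hold with margin at desk scale.

**Planted subtypes.** By default 16% of patients form subtype I with
strong deviations (+2.0 normative z units) and 84% form subtype II with
weak deviations (+0.3 z), on 12 of the 2K features drawn from 10
components: the fluctuation coefficients of components 1--9 and the
global efficiency of components 2, 6 and 10. Shifts stated in z units are
converted to parameter units as `z * 3.29 * sigma_param` (3.29 being the
5th-to-95th percentile span of a Gaussian), with sigma_param the
generator's own between-subject SD — so the planted z shift is nominal
and the realized shift is mildly attenuated by pipeline estimation noise.

**Demographics.** Ages uniform on [18, 50]; sex ~65% female; education
roughly N(12, 3.3) years clipped to [6, 22]; motion summaries mean FD ~
|N(0.07, 0.04)| mm with max FD a 3--8x multiple. Illness durations are
subtype-specific lognormals calibrated to means/SDs of 11.75 ± 12.09
months (subtype I) and 22.1 ± 23.92 months (subtype II), so subtype I has
the shorter durations. Only ranges and moments of the source cohort are
public; the distribution families are conventions.

## What the generator does and does not emulate

A green end-to-end test establishes that the pipeline recovers planted
low-rank dynamic-covariance structure, age trends, and deviation subtypes
under Gaussian sensor noise. It does not establish robustness to
hemodynamic confounds, scanner drift, motion artefacts, site effects, or
non-Gaussian physiological noise — none of which the generator emulates
(by design; see the package's scope).

Two transmission asymmetries are measured and documented rather than
hidden:

* *Fluctuation shifts transmit essentially undistorted* (the calibration
  above makes the fc channel linear), typically realizing ~70--90% of the
  nominal z shift.
* *Structural (efficiency) shifts attenuate substantially.* The guided
  estimator maximizes negentropy, and negentropy prefers sparse patterns:
  a densifier that makes a component denser is exactly what the logcosh
  contrast penalizes, so subject-specific densifier loadings are shrunk
  toward the group reference and the realized ge shift is a fraction of
  the nominal one. This is why the default subtype specification plants
  most of its shifts on the fluctuation channel.

# Estimation choices

**Fisher z before decomposition.** Variance stabilization of window
correlations; |r| is clamped at 1 - 1e-7 so z stays finite.

**Group ICA.** Subjects' window-by-edge matrices are stacked after
removing each subject's mean edge vector (the usual group-ICA convention;
without it, between-subject static-connectivity offsets dominate the PCA
and swamp the within-subject dynamics), columns are centred, the data are
reduced to K principal dimensions, and symmetric fixed-point logcosh ICA
is run over edges. Components are unit-norm, sign-fixed (largest-magnitude
loading positive) and ordered by fitted window-weight variance.

**Subject back-reconstruction.** The subject's centred dFC is whitened on
its full numerical rank (capped at W-1 and E-1). Two non-obvious choices
here, both forced by measurement: a top-K subject PCA is noise-dominated
at realistic SNR and loses most of the reference direction, while a
*complete* (rank-E) whitening basis provably erases all dependence on the
subject's data (the fixed-point map becomes basis-independent), so the
dimension must sit strictly between. The one-unit fixed point is
initialized at the reference projection and blended toward it with
`lambda_ref` (default 0.5); `lambda_ref = 1` returns pure projections.
Convergence tolerance 1e-6, at most 1000 iterations; non-convergence warns
and flags the component. Patterns whose max-entry sign convention is
flipped by noise are re-aligned to their reference so reference
similarities stay positive.

**Quantile curves.** Pinball-loss minimization by iteratively reweighted
least squares on a standardized age basis (numerically stable; raw-age
coefficients are reported by `tidy()`). Predicted quantiles are made
non-crossing by pointwise monotone rearrangement. Bootstrap CIs are
percentile CIs over `n_boot` resamples; they are reported but consumed by
nothing downstream, so the pipeline default is `n_boot = 0` while the
direct function default keeps 1000. Near-constant features can yield
degenerate (zero-width) quantile spans; `deviation_z()` raises an error
for them, and `score_cohort()` scores them as z = 0 with a warning so a
single degenerate feature cannot abort a cohort run.

**Forward selection.** The published selection criterion is not public;
mean silhouette is used because it is the quality index the results
report. Three safeguards make the greedy wrapper statistically sane:
(i) each of the 100 runs operates on a random 80% subject subsample (the
runs are "repeated cross-validation experiments"), so noise features
cannot accumulate high frequencies by winning a fixed-data tie
repeatedly; (ii) the first feature must beat a per-run parametric null —
the best silhouette of F standard-normal pseudo-features — because
2-means silhouette on pure 1-D noise already scores ~0.6; (iii) further
features are added while the criterion stays within 0.04 of its running
maximum, because mean silhouette is nearly invariant when a *redundant
informative* feature joins but drops sharply when a noise feature does. A
strict improve-only rule (the naive reading) can never select the second
of two equally informative features and was rejected for that reason.
Selection evaluations use best-of-3 k-means starts; the certainty stage
deliberately keeps single random starts, because run-to-run variability
is exactly what certainty quantifies.

**Certainty and diagnostics.** Runs are aligned to the first run by the
best cluster-label permutation. Certainty is `max_i n_i / n`; the final
label is the argmax with low-index tie-breaks. The exclusion threshold
defaults to 0.6 (the methods value; the results section of the source
study mentions 0.8 — both are one config field apart). Center instability
is the mean distance of per-run centers from their across-run mean, a
convention chosen because the cited definition is not accessible.

**Permutation tests.** Freedman--Lane: the observed statistic is the t of
the group term in `value ~ covariates + group`; null statistics permute
the covariate-only residuals, re-add the covariate fit, and recompute the
same adjusted t. p = (1 + #{|t*| >= |t|}) / (1 + n_perm), two-sided,
thresholded per feature at alpha = 0.01 with no further correction
(mirroring the source analysis; a Benjamini--Hochberg step is a one-liner
on the tidy output if wanted). With no covariates the scheme reduces
exactly to a plain permutation two-sample t-test.

**Ambiguities resolved as config switches.** The published head-motion
rule is a literal disjunction (mean FD <= 0.5 mm OR max FD <= 2 mm);
`fd_rule = "or"` is the default with `"and"` available. Window step "1"
is read as one volume, not one second. Rectangular windows are the
default with a Gaussian taper option.

# Degenerate inputs and numerical edges

* An all-zero component pattern has efficiency 0 (with a warning); a
  constant weight trajectory has fluctuation 0.
* A ROI constant within any window is an error naming subject, window
  and ROI.
* Constant ages are a design-rank error for the quantile fit; fitting
  with fewer than 10 x (degree + 1) points warns.
* k-means runs that produce an empty cluster are re-initialized (bounded
  retries).
* Reproducibility: every stochastic step takes a seed; the pipeline
  expands one root seed into named per-stage substreams, so the 100-run
  ensembles and the bootstrap are bit-reproducible.

# Known limitations

* The guided back-reconstruction is a behavioural stand-in for the exact
  published multi-objective optimization (whose details are in an
  inaccessible supplement): it preserves the two stated properties —
  independence maximization anchored to group references — with a
  deterministic, testable algorithm.
* Efficiency-channel deviations attenuate through estimation (see above);
  claims about structural subtype differences should lean on the
  permutation contrasts, not on the raw ge deviations.
* The normative model is age-only, matching the source design; sex and
  education enter only the group contrasts.
* Overlapping windows make successive dFC rows heavily dependent; the
  effective information for subject-level pattern estimation scales with
  T/L, not with the number of windows, which bounds how well any
  estimator can recover subject-specific edge loadings at T = 210.
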