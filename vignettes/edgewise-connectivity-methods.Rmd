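---
title: "Edge-wise functional connectivity group analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge-wise functional connectivity group analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edgeFC)
```

# The analysis model

edgeFC implements a whole-brain, edge-wise case–control analysis of
resting-state functional connectivity. Its unit of inference is the
*edge*: an unordered pair of parcellation regions. With the bundled
116-region atlas (90 cerebral regions, 45 per hemisphere, plus 26
cerebellar regions including the vermis) there are 116 × 115 / 2 = 6,670
edges, enumerated once in canonical upper-triangular order by
`edgeIndex()`; that ordering is the single source of truth for edge
identity across every stage.

Per subject, each region's representative series is the arithmetic mean
of its voxels' BOLD series (`extractRoiTimeseries()`), and each edge
receives the sample Pearson correlation of the two regional series and
its Fisher transform z = atanh(r) (`correlationMatrix()`, `fisherZ()`).
The Fisher transform is used for all testing because it approximately
normalizes and variance-stabilizes the correlation: for series with T
effectively independent samples, z is roughly Gaussian with variance
1/(T − 3) regardless of the true r.

Subject-level edge vectors are stacked into a `ConnectivityExperiment`
(a `SummarizedExperiment` with edges as rows and subjects as columns),
and an edge is declared *altered* between patients and controls when it
passes a conjunction of two criteria (`groupEdgeInference()`):

1. **Connectivity exists.** A two-tailed one-sample t test of the z
   values against zero within each group, Benjamini–Hochberg corrected
   at q = 0.01 across all edges of that group; the edge must pass in at
   least one group. This restricts the search to edges that represent
   real (positive or negative) coupling rather than noise around zero.
2. **Connectivity differs.** A two-tailed pooled-variance two-sample t
   test between groups with raw p < 0.01, *and* a permutation
   calibration: the observed statistic must be exceeded, in its own
   direction, in fewer than α = 0.01 of the repetitions of a
   within-control split null (below).

Selected edges are ordered by |t| and classified by
`classifyEdgeDirection()`: the *reference sign* is the sign of the mean
z in the group(s) that established criterion 1 (control preferred when
both pass and agree; a sign conflict between two passing groups yields
`unclassified`). A positive reference edge whose patient mean lies below
the control mean is a *decreased positive correlation*; a negative
reference edge whose patient mean is more negative is an *increased
negative correlation* (a deepened anti-correlation), and so on. This
separates, for example, weakened default-mode coupling from strengthened
task-negative/task-positive anti-correlation, which have different
interpretations even when both appear as "patients lower".

## The split-permutation null

The permutation correction asks whether a between-group difference of
the observed size could arise among exchangeable healthy subjects. The
control group is repeatedly partitioned at random into two pseudo-groups
(`half_split`: ⌊n/2⌋ vs ⌈n/2⌉ by default; a `ratio_matched` rule
proportional to the observed group sizes is available), and the same
pooled-variance t is recomputed per edge, yielding a per-edge empirical
null. The decision is one-tailed and sign-aligned: edge e is significant
when sign(t_obs) · t_null ≥ |t_obs| occurs in fewer than α·N of N
repetitions. The reported `perm_p` uses the add-one estimator
(1 + #exceedances)/(1 + N), which is never exactly zero and is bounded
below by 1/(N + 1); `perm_critical` is the empirical (1 − α)
order-statistic quantile of the aligned null.

Two properties are worth stating plainly. First, the null is built from
splits of the *control* group only, so its t statistics carry fewer
degrees of freedom (n_C − 2) than the observed comparison
(n_P + n_C − 2); the null is therefore slightly heavy-tailed relative to
the observed statistic's distribution, making the correction mildly
conservative. Second, the null is kept per edge rather than pooled
across edges, so edges with unusual control variance are calibrated
against themselves. Both choices mirror the procedure the analysis is
modeled on; under Gaussian data the per-edge permutation p agrees with
the analytic one-tailed t tail to within Monte-Carlo error at
N = 10,000, which the test suite checks.

All splits are drawn up front from one master seed, so results are
reproducible and independent of chunking or evaluation order.

## Preprocessing and quality control

Time-series denoising follows the conventional order: nuisance
regression first, then temporal filtering.

* `buildNuisanceDesign()` assembles intercept, linear drift, six rigid
  body motion parameters, and mean white-matter and CSF series (10
  columns when all are present); constant or collinear columns are
  dropped with a warning rather than silently inverted.
  `regressNuisance()` replaces each regional series by its OLS residual;
  residuals are orthogonal to every design column to ~1e-8 relative.
* `bandpassFilter()` is an *ideal* discrete-Fourier filter: frequency
  bins strictly outside [0.01, 0.08] Hz are zeroed (band edges
  inclusive), as is the DC bin. The ideal filter was chosen over an IIR
  design (e.g. Butterworth) because its pass/stop behavior is exact on
  bin-aligned sinusoids and it is idempotent, which makes the filtering
  contract directly testable; it is also what several rs-fMRI toolkits
  use. The high edge must lie below Nyquist = 1/(2 TR); at TR = 3 s that
  is 0.167 Hz.

Head motion QC (`motionSummary()`, `qcExclude()`) uses the standard
thresholds: exclusion when any-axis absolute translation exceeds 2.5 mm
or any-axis rotation exceeds 2.5°, or when mean point-to-point
translation exceeds 0.15 mm or rotation 0.1°. The framewise displacement
summary converts rotations to arc length with the conventional 50 mm
head radius (the metric's defining formula is not universal, and this
convention is stated rather than assumed). Rotations are degrees on disk
and in all thresholds; radians appear only inside the FD arithmetic.

## Behavioral correlations

For selected edges, `edgeScoreCorrelations()` correlates patient Fisher
z values with clinical/cognitive scores (MMSE, MoCA, PSQI, ISI, HAMA,
HAMD by default), reporting r, p, the uncorrected p < 0.05 verdict and a
BH-FDR verdict side by side — exploratory edge–behavior correlations in
modest cohorts rarely survive FDR, and showing both verdicts keeps that
visible instead of hiding it. The FDR family is the full edge × score
grid by default (`family = "grid"`); a per-score family is available.
Edge–score correlations are plain Pearson by default; covariate-adjusted
partial correlations (`partialPearson()`, residualizing both variables
on an intercept plus covariates, with n − k − 2 df) serve the
scale-to-scale analyses, e.g. sleep-quality vs cognition controlling for
age, sex and education. Binary covariates may be coded arbitrarily:
any affine coding gives the identical partial r.

# The synthetic cohort generator

No patient scans ship with the package; the generator
(`syntheticDesign()`, `simulateCohort()`) instead produces cohorts with
the statistical structure the analysis assumes, and its defaults *are*
the study conditions the pipeline targets: 39 patients vs 28 controls,
116 regions, 102 frames at TR = 3 s (a 5 min 6 s acquisition).

* **Covariance.** Group correlation matrices are assembled from blocks
  (`defaultBlocks()`): a default-mode-like block and a task-positive
  block at within-block r = 0.35 with −0.15 between them, and a
  cerebellar block at r = 0.25 coupled at +0.10 to the default-mode
  block. These values are in the range reported for within-network and
  anti-correlated-network resting-state correlations and give criterion 1
  a realistic mixture of clearly connected, anti-correlated and null
  edges. Injected altered edges overwrite single entries per group;
  `defaultAlteredEdges()` places five decreased-positive edges
  (z 0.55 → 0.05) inside the default-mode block and five
  increased-negative edges (z −0.15 → −0.65) across the anti-correlated
  pair, an effect of Δz = 0.5 in both cases.
* **Positive-definite repair.** Block-plus-overwrite matrices can be
  indefinite; they are repaired by eigenvalue flooring (minimum
  eigenvalue 1e-6) followed by re-normalization to unit diagonal, and
  the largest entry change is reported so tests can assert it is small.
  A side effect worth knowing: the repair (and subject jitter) slightly
  perturbs entries *near* an injected alteration, so a pipeline run on
  an altered cohort may legitimately select a few strong neighbors of
  the injected edges in addition to the edges themselves.
* **Subjects and time series.** Each subject's matrix is the group
  matrix jittered on the z scale (off-diagonal z + N(0, 0.1) by
  default, tanh back, re-repaired); the jitter models stable
  between-subject differences in coupling and is the dominant source of
  between-subject z variance beyond sampling noise. Series are AR(1)
  innovations (φ = 0.4 by default, mimicking band-limited BOLD
  autocorrelation) with stationary unit variance, colored by the
  Cholesky factor — the spatial mixing is frequency-flat, so the
  stationary cross-correlation equals the target matrix for any φ, which
  the tests verify empirically.
* **Motion.** Traces are cumulative sums of N(0, 0.02) increments (mm
  and degrees), giving point-to-point summaries comfortably inside the
  QC thresholds, as in a usable cohort.
* **Scores.** Baselines are Gaussian at anchors typical of an insomnia
  cohort versus controls (e.g. patient MMSE ≈ 26.9, PSQI ≈ 13.2 vs
  control 28.6 and 0.4), integer-rounded and clipped to each
  instrument's range. Dispersion anchors for the clinical scales are
  interpreted as standard errors and scaled by √n to subject-level SDs;
  age and education anchors are already SDs. For a score coupling
  (edge, score, target r), the patient score is rebuilt as
  μ + σ(r·u + √(1−r²)·ε⊥), where u is the sample-standardized realized
  Fisher z at that edge and ε⊥ is noise orthogonalized against u in the
  sample — the induced sample correlation then equals the target
  exactly before rounding, rather than merely in expectation, which
  makes recovery tests sharp without inflating the effect.

## What the generator does not emulate

Passing tests on synthetic cohorts show that the statistics do what they
claim under the model's assumptions; they do not certify behavior on
real scans. The generator omits: hemodynamic response shape and
voxel-level structure (region series are sampled directly), physiological
noise and its spatial correlation with networks, motion *artifacts* in
the series (motion traces are simulated but do not corrupt the data, so
nuisance regression removes essentially nothing), scanner drift beyond
the linear term, non-Gaussian and heavy-tailed BOLD fluctuations, and
any true coupling between symptom severity and connectivity beyond the
explicitly injected linear couplings.

# Numerical choices and degenerate inputs

* Correlations with |r| ≥ 1 − 1e-7 are clipped to ±(1 − 1e-7) with a
  warning before the z transform, keeping downstream t statistics finite
  while preserving auditability; exact |r| = 1 occurs only in degenerate
  (e.g. two-voxel synthetic) inputs.
* Zero-variance series are a hard error in `correlationMatrix()` (a
  constant series has no defined correlation); zero-variance *edges* in
  the test layer yield flagged NaN statistics and are never rejected by
  the FDR step.
* Regions with no voxels in a label volume are NA-filled and flagged,
  never dropped: silently shrinking the region set would change the
  6,670-edge geometry. Downstream connectivity refuses flagged panels
  until the user resolves them explicitly.
* The one-sample/two-sample tests use the textbook unbiased-variance
  formulas; BH-FDR is delegated to `stats::p.adjust(method = "BH")` and
  cross-checked against a brute-force step-up in the tests.
* Empirical permutation quantiles use the order statistic at
  ⌈(1 − α)N⌉ (no interpolation), so `perm_critical` is always an
  attained value of the null.
* The drift regressor is a centered linear ramp; the intercept is always
  retained in nuisance designs.

# Design choices where the procedure was open

* **Split sizes.** The permutation scheme only requires "a" split of the
  controls; `half_split` maximizes the df of each pseudo-comparison and
  is the default, with `ratio_matched` available. Both are documented
  approximations of an under-specified step.
* **FDR reading.** "p < 0.01, FDR corrected" is read as BH at level
  q = 0.01 within each group across all 6,670 edges.
* **Criterion 2 conjunction.** The raw two-sample p < 0.01 *and* the
  permutation decision are both required; the permutation is read as a
  calibration of the same test, not a replacement.
* **Order of operations.** Nuisance regression precedes band-pass
  filtering, following the conventional listing of the two steps.
* **Direction tie-break.** When both groups pass criterion 1 with
  agreeing signs the control mean anchors the reference sign; a sign
  disagreement is surfaced as `unclassified` rather than resolved
  silently.

# Problem sizes used in the shipped checks

The package's own test suite runs the full two-criterion selection at
the complete study scale (39/28 subjects, 116 regions, 6,670 edges,
102 frames) with the permutation count scaled to 2,000 splits per run:
ten null-cohort seeds for calibration (selected fraction ≤ 1% expected)
and ten altered-cohort seeds for recovery of the ten injected edges with
direction classification. Oracle-agreement checks run the permutation
null at the full N = 10,000. The acceptance script repeats the same
computations at three seeds each plus ten/twenty behavioral replicates.
These sizes are the package's reproducibility compromise: large enough
that calibration and recovery are meaningfully exercised, small enough
to rerun routinely.

# Known limitations

* The pipeline operates on region-level series; image-level steps
  (slice timing, realignment, spatial normalization) are upstream and
  out of scope, as are scrubbing/censoring of high-motion frames.
* The group comparison is unadjusted (no covariates at the edge level),
  matching the modeled procedure; covariate adjustment is available only
  in the behavior module.
* The permutation null's df mismatch (above) makes criterion 2 slightly
  conservative for unequal group sizes.
* Partial-correlation or precision-based connectivity, dynamic
  connectivity, and graph-theoretic summaries are deliberately not
  provided.

# Session info

```{r}
sessionInfo()
```
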