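---
title: "Hemispheric functional-connectivity asymmetry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hemispheric functional-connectivity asymmetry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemifc)
```

## The analysis

`hemifc` analyses hemispheric asymmetry of resting-state functional
connectivity (FC) from parcellated ROI time series, the setting typical of
unilateral mesial temporal lobe epilepsy studies where the side of the
seizure focus (left vs right hippocampal sclerosis) is expected to shape
the FC of each hemisphere differently. The pipeline is:

1. **Connectivity.** For each subject, Pearson correlations between every
   pair of ROI time courses, Fisher-transformed (`z = atanh(r)`) for
   parametric group statistics (`compute_connectivity()`).
2. **Edge-wise group contrasts.** Per ROI pair, a two-sample t-test on the
   z values between two groups; an edge is *significant* under a two-level
   rule: uncorrected p below a height threshold (default 0.01), then
   Benjamini–Hochberg FDR below 0.05 within each seed ROI's candidate
   edges (`compare_edges()`).
3. **Hemispheric aggregation.** For each lateral ROI, `rFC` (`lFC`) is the
   sum of absolute connection weights over the ROI's supra-threshold edges
   (`r > 0.25`) to right- (left-) hemisphere targets
   (`hemispheric_fc()`).
4. **Asymmetry index.** `AI = 100 (rFC − lFC) / ((rFC + lFC)/2)`, positive
   = rightward, bounded in [−200, 200], undefined when both aggregates are
   zero (`asymmetry_index()`).
5. **Group testing.** Within-group lateralization (paired t of rFC vs lFC
   per ROI, FDR across ROIs within group); between-group AI comparison
   (one-way ANOVA per ROI, FDR across ROIs, Bonferroni pairwise post hocs
   on the pooled within-group mean square); Pearson correlations of FC/AI
   features with onset age and disease duration, FDR across all tested
   pairs; demographic battery (ANOVA on age, χ² on sex, Mann–Whitney U on
   onset/duration).
6. **Reporting.** Counts and percentages of ROIs participating in
   significant edges (half-up rounding to 2 decimals) and
   rightward/leftward tallies of lateralized ROIs.

Because no ROI time-series data are deposited for this kind of study, the
package ships a first-class synthetic cohort generator that is itself part
of the tested surface; every downstream claim is validated against cohorts
with known structure.

## The atlas

The bundled atlas (`default_atlas()`) is a 105-region reconstruction of a
Harvard–Oxford-style cortical + subcortical parcellation: 43 lateral
cortical pairs, 7 subcortical pairs (50 L / 50 R, homotopic pairing a
perfect matching) and 5 midline regions (frontal medial cortex,
subcallosal cortex, anterior and posterior cingulate, precuneus). It is a
*synthetic stand-in*: region names and counts follow the conventional
parcellation, but no coordinates or volumes are represented, and all
statistics are atlas-agnostic — any table with columns
`roi_id / name / hemisphere / homotopic_partner` loads via `load_atlas()`.
Hemisphere membership is declared, never inferred: the package never
touches image space. Midline regions are excluded from all lateralized
statistics by `lateral_subset()` and never contribute as targets.

One reading ambiguity is deliberately left open: whether hemispheric
aggregation runs over all lateral ROIs or only those pre-selected by the
edge-wise contrasts. Published counts of "ROIs entering the asymmetry
analysis" are not always arithmetically reconcilable with the midline
exclusion, so `profile_cohort(roi_subset = ...)` exposes the selection as
an explicit filter (default: all lateral ROIs) and the package asserts
neither reading.

## Threshold and weight semantics

"Strongly correlated (threshold at r > 0.25)" is read literally as a
signed threshold on raw r — only positive connections count — with
`mode = "absolute"` (|r| > 0.25) available since summed *absolute* values
support either reading. The summed weight is |z| by default (the
transformed scores are what enter analysis); `weight = "r"` sums |r|
instead. The ROI's homotopic partner is an ordinary target. All four
combinations are tested against a literal loop-over-pairs reference.

## The synthetic cohort model

A `cohort_design()` states the simulated world:

* **Group sizes** default to 12 / 11 / 23 (left-focus, right-focus,
  controls) and **series length** to 230 (240 acquired volumes minus 10
  discarded for signal stabilization) — the cohort geometry of the
  motivating study design.
* **Population correlation structure**: within-hemisphere baseline 0.35,
  homotopic coupling 0.6, and a cross-hemisphere baseline. These defaults
  are ordinary magnitudes for ROI-averaged BOLD correlations: homotopic
  pairs are reliably the strongest long-range connections, and 0.35 keeps
  baseline edges clearly above the 0.25 aggregation threshold.
* **Entry heterogeneity** (`correlation_jitter`, SD 0.02): real covariance
  is never block-uniform. The jitter is assigned per hemisphere-swap orbit
  (mirror pairs perturb identically, homotopic entries exempt), so a
  zero-profile design is *exactly* invariant under swapping every
  homotopic pair, and it is a pure function of the design seed. It also
  keeps the AI-target search well posed: with perfectly uniform blocks,
  whole edge sets cross the aggregation threshold at the same scaling
  multiplier and mid-range AI targets fall into unattainable jumps.
* **Temporal model**: shared-coefficient AR(1) (default 0.3, a typical
  effective autocorrelation for repetition times around 2 s) on
  innovations scaled by `1 − φ²`, so the stationary cross-sectional
  covariance equals the population matrix exactly. Band-pass filtering,
  hemodynamics, motion and scanner noise spectra are *not* emulated.
* **Clinical covariates**: truncated-at-zero normal draws per group (age
  25.17 ± 3.69 / 29.25 ± 9.92 / 31.82 ± 10.25; onset 16.42 ± 8.61 /
  19.09 ± 8.81; duration 12.83 ± 8.68 / 12.73 ± 6.53 years; male fractions
  9/12, 6/11, 13/23). Onset and duration are drawn independently — their
  real dependence is unknown.

### The balanced null

The calibration property — the paired rFC-vs-lFC t-test rejects at the
nominal rate under a design with zero asymmetry — is not automatic. An
ROI's own hemisphere offers one fewer target than the opposite hemisphere
(which contains the homotopic partner), so a uniform baseline is *not* a
lateralization null. When `cross_correlation = NULL`, the package solves

\[(n-1)\, g(b_\text{within}) = g(b_\text{homotopic}) + (n-1)\, g(b_\text{cross})\]

for the cross-hemisphere baseline, where `g(ρ)` is the *expected*
supra-threshold edge weight under sampling (`expected_edge_weight()`),
computed with the Fisher-z normal approximation including its O(1/T) mean
bias and the AR(1) variance inflation `(1+φ²)/(1−φ²)`. Expectation is
linear, so edge dependence is irrelevant to the balance. The solve needs
equal hemisphere sizes and enough lateral ROIs for the homotopic term to
be absorbable (roughly `(n−1) g(b_w) > g(h)`); tiny test atlases pass an
explicit `cross_correlation` instead. Calibration tests additionally set
`correlation_jitter = 0`: heterogeneity is itself genuine per-ROI
lateralization, i.e. part of the alternative, not the null.

### AI targeting

Per-ROI AI targets are realized by bisection on a two-sided multiplier of
the ROI's hemispheric blocks — right-target entries scaled by `m` as
left-target entries scale by `1/m` — with the positive-semidefinite repair
(spectral clip + diagonal rescale, `nearest_correlation()`) evaluated
*inside* the search objective. Two details matter:

* One-sided scaling exits the PSD cone for large targets (a single row
  cannot correlate at ≈0.63 with 49 variables that inter-correlate at
  0.35), and a repair applied after the fact destroys the target. The
  two-sided multiplier stays feasible and the in-objective repair makes
  the measured AI the AI of the matrix actually returned.
* The objective is the **expected sampled AI** at the design's series
  length, not the hard-thresholded AI of the population matrix. Whenever
  targeting pushes entries near the 0.25 threshold, sampling smears edges
  across it and the hard-thresholded population AI becomes a biased
  predictor of what cohorts will show; the expectation model absorbs
  this. The two coincide (within the 2-unit contract) in designs whose
  entries stay clear of the threshold, e.g. baselines 0.5 / 0.7.

A final Monte-Carlo calibration (`calibrate_ai = TRUE`) simulates 120
subjects from the candidate matrix, measures the cohort-mean estimated AI
and applies up to two damped retargeting steps (factor 0.6 — profiled ROIs
interact, and a full Newton step overshoots near the threshold). The step
is deterministic given the design seed. Infeasible targets (e.g. any
mid-range AI for an ROI with no same-hemisphere targets) raise a classed
error reporting the achievable range.

## Numerical and statistical choices

* **Fisher transform**: r clamped to ±(1 − 1e−12) before `atanh`, so
  perfectly correlated columns give large finite scores; z diagonal stored
  as 0 and never used.
* **Edge contrasts**: pooled-variance Student t by default (the classical
  second-level GLM convention); Welch by flag. No nuisance covariates.
* **Two-level edge significance**: the cluster-style extent correction is
  approximated as seed-level FDR — BH over *all* edges incident to the
  seed, intersected with the height threshold — the documented
  ROI-analysis analogue, with every pair judged in both endpoints'
  families (reported q is the smaller; significance is the OR). Running
  BH over only the height-thresholded candidates instead
  (`fdr_scope = "seed_candidates"`) is strictly more liberal: a lone
  candidate is judged against itself and always survives, which destroys
  null control at full atlas size; it is kept as an auditable option, as
  is plain matrix-wide BH (`fdr_scope = "matrix"`).
* **BH-FDR**: step-up with enforced monotonicity, missing p-values passed
  through, input order preserved; equals the literal textbook rule and
  `p.adjust(method = "BH")` on every tested input.
* **Post hocs**: pairwise t with the omnibus pooled MSW and its degrees of
  freedom (classical Bonferroni post hoc convention); per-pair Welch by
  flag. Bonferroni = raw p × number of pairs, capped at 1.
* **FDR families** (a logged choice, since family definitions are rarely
  printed): lateralization q within group across ROIs; AI-ANOVA q across
  ROIs; clinical-correlation q across all (feature, covariate) pairs.
* **Mann–Whitney U**: first-sample-wins convention; exact enumeration of
  the U null distribution for ≤ 8 per group without ties, otherwise the
  normal approximation with tie correction and continuity correction.
* **Degenerate inputs** (zero-variance differences, constant vectors,
  empty χ² margins) raise classed errors rather than returning p of
  exactly 0 or 1; undefined AI values are dropped listwise per ROI with
  counts kept (`n_dropped`).
* **Rounding**: printed percentages use half-up rounding to 2 decimals,
  reproducible as `floor(10000 k / n + 0.5) / 100`.

## What a green test establishes — and what it does not

The generator emulates a stationary Gaussian world with a single shared
AR(1) coefficient and exact covariance control. Green calibration, power
and recovery tests therefore establish that the *estimation pipeline* is
correct and well calibrated under that world. They do not establish
robustness to non-stationarity, motion artifacts, filtering-induced
autocorrelation structure, hemodynamic variability, or atlas
misregistration — none of which are modelled. The acceptance checks on
printed percentages and tallies verify the reporting arithmetic, not the
reproduction of any real-data edge list, which would require the original
scans.

## Known limitations

* The balanced-null solve assumes equal hemisphere sizes and the Fisher-z
  approximation; residual type-I distortion is empirically within the
  tested band but not exactly zero.
* AI targets realize the cohort *mean*; the per-subject AI distribution
  around strong targets is wide (SD ≈ 20 AI units at T = 1000 for ±60)
  and mildly skewed near the ±200 bounds.
* Only three group labels (HC, LMTLE, RMTLE) are modelled, matching the
  three-group design the statistics serve.
* The per-seed FDR approximation to cluster-extent correction is a
  documented stand-in; with every pair in two families its false-discovery
  behaviour is slightly more liberal than a single BH pass.
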