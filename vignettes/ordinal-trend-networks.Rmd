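---
title: "Deriving treatment-responsive fALFF covariance networks with ortcva"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving treatment-responsive fALFF covariance networks with ortcva}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ortcva)
```

## The scientific problem

Stereotactic treatments such as MR-guided focused-ultrasound thalamotomy
for essential tremor change the brain's spontaneous activity at the level
of distributed networks, not single voxels. A within-subject spatial
covariance approach asks: *is there a single spatial pattern whose
expression in each patient increases from the pre-treatment scan to the
post-treatment scan, in as many patients as possible?* The input is one
fractional amplitude of low-frequency fluctuation (fALFF) map per patient
per timepoint; the output is a voxel-weight pattern, one expression score
per scan, and resampling-based evidence that the ordinal trend is not a
chance arrangement.

`ortcva` implements that pipeline end to end:

1. **fALFF** maps from 4D series (`compute_falff`, `standardize_map`),
2. **pattern derivation** by ordinal-trend canonical variates analysis
   (`ort_cva`), with permutation inference (`permutation_test`), a
   bootstrap voxel-reliability z-map (`bootstrap_zmap`) and leave-one-out
   validation (`loo_validation`),
3. **prospective scoring** of new scans against a frozen pattern —
   the topographic profile rating (`compute_tpr`, `batch_tpr`,
   `predict()`),
4. **regional characterization** of the z-map (`aggregate_to_atlas`,
   `top_fraction`, `threshold_clusters`, `extract_region_means`),
5. **clinical statistics** (`cohens_d`, `percent_improvement`,
   `spearman_correlation`, `two_sample_t`, `fit_longitudinal_lmm`),
6. **imaging transcriptomics**: PLS1 of a regional gene-expression matrix
   on the regional pattern profile (`fit_pls1`, `pls_permutation`,
   `bootstrap_gene_weights`, `enrichment_ora`),
7. a **synthetic-cohort generator** with known ground truth
   (`cohort_config`, `simulate_cohort`, `simulate_falff_panel`,
   `make_atlas`, `simulate_gene_expression`), because clinical resting-
   state data of this kind cannot be publicly archived; every stage of the
   package is testable against planted truth.

## The model

### fALFF

For a voxel time series $x_t$ ($t = 1..T$, repetition time $\tau$), let
$A(f)$ be the amplitude spectrum of the mean-removed series. fALFF is the
band amplitude fraction

$$\mathrm{fALFF} = \frac{\sum_{f \in [f_1, f_2)} A(f)}
                        {\sum_{0 < f \le 1/2\tau} A(f)},$$

with the conventional band $f_1 = 0.01$, $f_2 = 0.08$ Hz by default. Bin
inclusion is half-open. It is invariant to scaling and offsets of the
series; a white-noise series has expected fALFF equal to the fraction of
frequency bins in the band (0.28 for TR = 2 s). Maps are z-scored within
the mask by default before pattern analysis, which removes subject-level
global scale.

### Ordinal-trend canonical variates analysis

Scans form a subject $\times$ ordered-condition panel over a common mask.
Write $x_{sc}$ for the map of subject $s$ in condition $c$, $\bar{x}$ for
the grand mean map. The fit:

1. center: $y_{sc} = x_{sc} - \bar{x}$; subject-center:
   $w_{sc} = x_{sc} - \bar{x}_s$;
2. for each mixing weight $w$ on a small grid in $[0,1]$, decompose
   $Z_w = w\,Y + (1-w)\,W$ by SVD and retain the smallest number of
   principal components reaching 50% cumulative variance (capped at
   $S - 1$);
3. in the retained PC-score space, take the canonical direction
   $a = \Sigma_W^{-1} d$, where $d$ is the regression of the condition
   means on the condition rank and $\Sigma_W$ the within-subject,
   within-condition residual covariance;
4. map back to voxel space, normalize to unit norm, and orient the sign so
   mean expression increases along the condition order;
5. expression of any scan is
   $e(x) = \langle x - \bar{x},\, \mathbf{w}\rangle$; a **violator** is a
   subject whose expression sequence is not strictly increasing (ties
   violate);
6. the mixing weight with the fewest violators wins; ties go to the larger
   paired $t$ of the last-vs-first expression change.

Two numerical choices deserve note. First, $\Sigma_W$ is estimated with
only $(S-1)(K-1)$ degrees of freedom; raw inversion amplifies
near-zero-variance PC directions and destroys pattern fidelity, so the
whitening uses shrinkage toward an isotropic target,
$(1-\gamma)\Sigma_W + \gamma\,\overline{\mathrm{tr}}\,I$ with
$\gamma = 0.1$ (`shrink`). Under the package's default synthetic
conditions the first PC already carries the trend and $k = 1$, where the
shrinkage is inert. Second, a panel whose within-subject variance is
*exactly* zero (noise-free simulations) is not rejected: the canonical
direction falls back to the unwhitened between-condition direction, which
is the $\gamma \to 1$ limit; only panels with neither within-variance nor
between-condition separation are refused.

All refits run in row-space coordinates after one thin SVD of the centered
scan matrix. Permuting labels, resampling subjects, or dropping a subject
keeps the data inside that row space, so results are identical to
voxel-space fits while a 1000-permutation test costs seconds.

### Inference

**Permutation test.** Condition labels are shuffled independently within
each subject and the *entire* fit — including the mixing-weight selection —
is re-run per draw. The test statistic is the violator count; because its
null distribution concentrates on a few small integers (the adaptive fit
orders most subjects even under permutation), ties are broken by the
paired $t$ statistic of the expression change, the same tie-break the fit
itself uses. The add-one estimator
$p = (1 + \#\{\text{null at least as extreme}\}) / (1 + n_\text{perm})$
never returns zero. Under null simulations the rejection rate at
$\alpha = 0.05$ is close to nominal (measured 0.04 over 200 cohorts); the
bare violator count without tie-breaking is so discrete that it can
essentially never reject.

**Bootstrap z-map.** Subjects are resampled with replacement (500 draws by
default), the pattern refit and sign-aligned per draw, and
$z(v) = \mathbf{w}(v) / \mathrm{SD}_\text{boot}(\mathbf{w}(v))$. Draws
with fewer than three distinct subjects are redrawn. The z-map is the
reliability-weighted topography used by all regional analyses.

**Leave-one-out.** Each subject is held out, the pattern refit, and the
held-out scans scored with the fold pattern; the fold-pattern correlation
matrix quantifies topographic stability.

### Scoring new scans

The topographic profile rating of a scan is its expression
$e(x)$ under a *frozen* pattern; standardized scores anchor to the
derivation baseline scores (mean 0, SD 1 at baseline), so post-operative
shifts read directly as baseline-referenced effect sizes. The reference is
stored with the pattern; an external control reference can be substituted
by editing `score_reference`.

### Regional characterization

The z-map is averaged within atlas regions; regions are ranked by
$|\bar{z}|$ and the top `ceiling(0.1 * R)` flagged (mean rather than sum,
so region size does not dominate; ties at the boundary break by region
id). Voxel-wise, suprathreshold voxels at $|z| > 1.96$ are labelled by
connected components — positive and negative exceedances separately,
26-connectivity by default — and components under 50 voxels are discarded.

### Longitudinal clinical statistics

Tremor ratings and expression scores are compared with paired/pooled
Cohen's d, baseline-anchored percent improvement, Spearman correlation
(average ranks, two-sided t-approximation p), Welch two-sample t, and a
random-intercept linear mixed model
`value ~ timepoint + (1 | subject)` fit by REML (lme4), with a Wald
omnibus test and per-level contrasts against baseline using the normal
approximation. Satterthwaite fractional degrees of freedom are
deliberately not reproduced; with the cohort sizes involved the normal
approximation is adequate, and the balanced two-level contrast agrees with
the paired t-test (verified in the tests). Post-hoc contrasts are
unadjusted by default (Holm available via `adjust`).

### Imaging transcriptomics

PLS1 relates a regions $\times$ genes expression matrix (genes z-scored
across regions internally) to the regional pattern profile: the first
component's gene weights are proportional to the gene–response
covariances; variance explained is the squared score–response correlation.
Significance comes from permutation of the response — uniform shuffling,
or the **spin** procedure: region centroids are projected to the unit
sphere, randomly rotated, and values reassigned by greedy bijective
nearest-centroid matching, which preserves the response's value multiset
and, approximately, its spatial autocorrelation. Gene contributions are
ranked by bootstrap z (regions resampled with replacement), and the top
genes fed to hypergeometric over-representation with
Benjamini–Hochberg-adjusted q values.

Two measured properties matter for interpretation. With spatially smooth
(realistic) noise genes and a smooth response, *shuffle* permutation is
strongly anticonservative (rejection ~0.95 at nominal 0.05 in our null
simulations) — this is the spatial-autocorrelation problem the spin test
addresses, and the reason reports of PLS significance can evaporate under
spatial correction. Shuffle calibration holds under the exchangeable null
(white noise genes, `smooth_noise = FALSE` in the generator). Second,
under a pure null the bootstrap gene z-scores are over-dispersed relative
to N(0,1) by a factor of roughly 1.5, because bootstrap draws share ~63%
of regions with the observed sample; the z is a ranking statistic, not a
calibrated test statistic.

## The synthetic-cohort generator

`simulate_cohort` / `simulate_falff_panel` generate what the pipeline
consumes, with the ground truth retained:

- **Geometry**: an ellipsoidal mask in a 16^3 voxel grid (about 1,500
  in-mask voxels); a deterministic two-lobed Gaussian pattern (positive
  and negative lobe) of unit norm with compact support.
- **Signal**: each scan is a sum of three in-band sinusoids
  (0.02/0.04/0.06 Hz) and two out-of-band sinusoids (~0.15/0.20 Hz), all
  snapped to the exact DFT grid of the series so band amplitude sums are
  exact. The in-band amplitude at voxel $v$ is
  $A_0 (1 + h(v)) + e_{st}\, p(v)$ — baseline, a static smooth
  "anatomical" profile $h$, and the planted expression times the pattern —
  while the out-of-band amplitude carries the complement so the total
  spectral amplitude is constant. fALFF is therefore *exactly affine* in
  the planted expression, and with zero noise the post-minus-pre fALFF
  difference maps are exactly proportional to the pattern.
- **The anatomical profile** is shared by every scan and orthogonalized
  against the pattern within the mask. It has a methodological purpose:
  per-map z-scoring divides by the in-mask SD, and in a one-pattern world
  without static structure that SD is driven by the signal itself, which
  nullifies expression differences. Real fALFF maps are dominated by
  stable anatomy; the profile restores that property, and the
  orthogonalization keeps the planted truth identifiable.
- **Expression**: subject baseline expressions are N(0, 0.3); a
  `responder_fraction` of 0.9 (22 of 24 subjects) gains `effect_size` =
  0.5 pattern-units per month; the rest stay flat. Per-frame white noise
  has SD 0.1 against a baseline oscillation amplitude of 1. Under these
  defaults the paired effect size of the expression change at 6 months is
  about 3.2 and the fitted pattern's cosine with truth about 0.97 — the
  strong-effect regime reported for thalamotomy cohorts.
- **Clinical scores**: hand tremor and CRST-like subscores are affine
  decreasing functions of true expression plus noise, truncated at zero,
  with slopes sized so baseline-to-6-month hand-tremor improvement is
  roughly 75–80% and the paired d near −3.
- **Atlas and genes**: `make_atlas` grows contiguous regions from random
  seeds within each hemisphere (first-axis midline split; no region
  straddles it). `simulate_gene_expression` plants `n_causal` genes that
  covary positively with a per-region profile; remaining genes are smooth
  spatial random fields (or white noise under `smooth_noise = FALSE`).

What the generator does **not** emulate: head motion, physiological
noise, scanner drift, spatial smoothing, registration error, multi-site
effects, and any spatial covariance structure beyond one pattern plus a
static profile. Passing tests on these cohorts demonstrates that the
implementation recovers known truth under its stated assumptions; it does
not certify performance on real patient data.

## Problem sizes used by the test suite

Simulation sizes are chosen so the whole suite runs on one CPU core in
minutes: pattern-recovery replicates use the full default cohort
(24 subjects, 16^3 grid, 120 volumes, 200 permutations, 50 replicates);
null calibration uses 200 cohorts of 24 subjects on a 10^3 grid with 64
volumes; mixed-model recovery uses 100 datasets of 50 subjects; PLS
recovery uses 20 gene-matrix replicates over a 60-region atlas.

## A worked derivation

```{r example, eval = FALSE}
library(ortcva)

cfg <- cohort_config(timepoints = c(0, 1, 3, 6), seed = 1)
sim <- simulate_falff_panel(cfg)

derivation <- scan_panel(sim$panel$data[, c(1, 4), ],
                         sim$panel$subject_ids, c("m0", "m6"),
                         mask = sim$mask)
fit <- ort_cva(derivation, seed = 1)
print(fit)
permutation_test(fit, n_permutations = 1000)$p
zmap <- bootstrap_zmap(fit, n_bootstrap = 500)

atlas <- make_atlas(cfg$grid_dims, n_regions = 246, mask = sim$mask)
head(top_fraction(aggregate_to_atlas(zmap$zmap, atlas), 0.1))
```

## Known limitations

- The derivation internals (PC retention, covariance mixing, shrinkage)
  are one concrete realization of the ordinal-trend family of methods;
  other published variants differ in the PC-selection rule and the
  permutation statistic.
- The permutation test's tie-broken statistic is near-exact under
  exchangeability but still discrete at very small sample sizes.
- `fit_longitudinal_lmm` reports normal-approximation contrasts; for very
  small cohorts a Satterthwaite or Kenward–Roger correction (e.g. via
  lmerTest) would be more conservative.
- Spin permutation on synthetic atlas centroids approximates, but does not
  reproduce, spin tests on real cortical surface coordinates.
- The generator's single-pattern world understates the rank of real
  between-subject covariance; cosine-recovery numbers on synthetic data
  are upper bounds on what real data would give.
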