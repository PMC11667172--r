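---
title: "Modeling inter-subject idiosyncrasy at the dyad level"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling inter-subject idiosyncrasy at the dyad level}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadak)
```

## The question and the model

The Anna Karenina (AnnaK) hypothesis for a trait says that people at one
end of the scale are alike while people at the other end are each
different in their own way. Operationally: take any per-subject feature
(a connectivity profile, a gaze trajectory, a document embedding), compute
a dissimilarity for every unordered pair of subjects, and ask whether
dyads made of two high-trait members (HH) are more dissimilar than mixed
(HL) and low-low (LL) dyads, and whether dissimilarity increases with the
dyad's mean trait.

`dyadak` implements that pipeline end to end for the mentalizing setting
in which it was developed — perspective-taking (PT) scores from the IRI
subscale (range up to 28, median-split with ties going to the low group),
six mentalizing-network ROIs observed for 151 movie TRs, gaze at 24 fps
on a 1280 x 790 frame, 768-dimensional sentence embeddings — but every
constant is a parameter.

## Dissimilarity indices

All indices are dissimilarities (larger = more idiosyncratic):

* **Time dynamics**, per region: `1 - r` between the two subjects' time
  series; bounded by [0, 2].
* **FC profile**: each subject's region-by-region Pearson correlations are
  Fisher z-transformed (`atanh`), the strict upper triangle is vectorized
  in row-major order, and the dyad value is the Euclidean distance between
  the two edge vectors. Per-edge values are `|z_i - z_j|`, so the squared
  global distance is exactly the sum of squared per-edge values — a
  decomposition the test suite checks to 1e-10. Correlations with
  `|r| >= 1 - 1e-7` (numerically perfect, possible in short synthetic
  series) are clamped before `atanh` with a warning; the FC diagonal is
  stored as 0 and never enters any sum.
* **Strength centrality**: the row sums of the off-diagonal z-matrix;
  global and per-region dissimilarities as for the FC profile.
* **Gaze**: traces are preprocessed first — missing runs of at most
  `gap_frames` (default 1 frame, i.e. under 75 ms at 24 fps) flanked by
  valid samples are linearly interpolated; longer runs are blinks and are
  invalidated; samples outside the video frame are invalidated with their
  coordinates left untouched. The stated blink threshold of 75 ms equals
  about 1.8 frames at 24 fps, so "2 frames or more" is the operative rule;
  both thresholds are arguments. Preprocessing is idempotent, which the
  suite verifies. The dyad value is `1 - (r_x + r_y)/2` on the frames
  where *both* traces are valid; dyads whose joint overlap falls below 10%
  of frames (an added guard — tiny intersections make `r` meaningless) are
  rejected and flagged rather than silently imputed.
* **Semantic**: `1 - cosine` between embedding vectors. Embeddings are
  consumed as-is; the bundled `toy_embedder()` (L2-normalized term
  frequencies over a fixed vocabulary) exists only so tests and examples
  run without a sentence-embedding model and is not a substitute for one.

Per index, subjects whose mean dissimilarity with all others is more than
3 SD from the sample mean (|z| > 3, single pass, no re-iteration) are
excluded before dyads are formed.

## The dyadic mixed model

Dyad-level observations are not independent: every subject sits in n - 1
dyads. The common remedy in the inter-subject similarity literature is to
"double" the data (each dyad appears once per member ordering) and fit
crossed random intercepts for "participant 1" and "participant 2".
`dyadak` fits the model that recipe is aiming at, in its exact symmetric
form: one row per unordered dyad and a single participant effect entering
through both members,

$$d_{ij} = x_{ij}'\beta + a_i + a_j + e_{ij}, \qquad
  a_s \sim N(0, \sigma_a^2),\; e_{ij} \sim N(0, \sigma_e^2),$$

so the marginal covariance is $V = \sigma_e^2 I + \sigma_a^2 Z Z'$ with
$Z$ the dyad-by-subject incidence matrix. The fit profiles the variance
ratio by REML (ML optional) and uses the thin SVD of $Z$, so solves stay
in subject-dimensional space and a 1485-dyad fit takes milliseconds.

Why not fit the doubled data literally with `(1|id1) + (1|id2)`? Two
quantifiable distortions, both measured during development on
trait-independent ("null") synthetic cohorts at n = 20:

1. duplicated rows carry no new information, halving the apparent
   fixed-effects covariance (type-I error 0.12-0.15 at nominal 0.05);
2. even after rescaling the covariance by 2, splitting each participant
   into two *independent* role effects gives zero model covariance to
   dyad pairs that share a subject in opposite roles, where the truth is
   $\sigma_a^2$ (residual type-I error around 0.08).

The symmetric model needs no rescaling, is invariant to member ordering
by construction (the suite checks estimates to 1e-8 under arbitrary
swaps), and brought the measured type-I error to about 0.07 at n = 20 —
see the calibration note below.

The dependent variable and all continuous predictors are z-scored over
the modeled dyads, so coefficients are standardized. Dyad groups are
treatment-coded against LL; because the fixed effects are additive
(group plus covariate factors, no interactions), the pairwise contrasts
HH−HL, HH−LL and HL−LL computed as marginal-mean differences are exactly
coefficient differences, and equal-versus-observed weighting over
covariate levels makes no difference — which is why the package exposes
no weighting option. Contrasts are Wald t-tests with
Benjamini–Hochberg correction within the three-contrast family (the
pipeline additionally adjusts across all indices of a run as
`p_fdr_family`).

**Degrees of freedom.** Following the convention of the dyadic ISC
literature, p-values use df = N − k, where N is the number of unique
dyads and k counts the focal predictor only (k = 1; `k_convention =
"all"` counts every non-intercept column instead). With 1485 dyads and
k = 1 this gives df = 1484. Note that when the participant variance
dominates, the information about a group contrast is limited by the
number of subjects, not dyads, so at small n this df convention remains
mildly liberal: across 300 null cohorts of 20 subjects the HH−LL
rejection rate at the 0.05 level was about 0.07 (the t statistic's
standard deviation is 1.00, but its tails are heavier than
$t_{189}$). The convention is kept because it is the field's reporting
standard; analyses at 20 or fewer subjects should read borderline
p-values accordingly.

**Confounds.** Candidate covariates are screened by either arm — Pearson
correlation with the trait, or a high/low group difference (t-test for
continuous, chi-square for categorical), each at alpha = 0.05. Screened
confounds enter the group model as dyad-level HH/HL/LL factors from their
own median splits, and the continuous model as dyad means. Before Mantel
tests the confound dyad means are regressed out of each index by OLS.

**Mantel tests.** The correlation between two dissimilarity matrices is
assessed by jointly permuting the rows and columns of one matrix. The
observed statistic is included in the null count, so
p = (1 + #extreme)/(1 + n_perm) is never zero; the default alternative is
one-sided "greater" because the substantive hypotheses are directional.
`exact = TRUE` enumerates all n! relabelings (guarded at n <= 8) and is
cross-checked in the tests against an enumeration written independently
of the package, and against `vegan::mantel` for the statistic. Reported
degrees of freedom follow the correlation convention n − 2 over retained
subjects.

**Network interaction.** The 3 (dyad group) x 2 (network) test stacks the
two networks' values in long format, doubles the rows, and fits
`lmerTest::lmer(value ~ group * network + (1|id1) + (1|id2))`, reporting
the Satterthwaite-approximated interaction F (a likelihood-ratio
chi-square is the fallback when the approximation degenerates). This one
test intentionally keeps the doubled-data form: its printed fractional
denominator df matches how such interactions are conventionally reported,
and the suite requires of it only F ≈ 0 for identical inputs, label-swap
symmetry, and power against structure confined to one network — the
doubling optimism is acknowledged rather than corrected here.

## The synthetic-cohort generator

The generator exists so that every stage of the analysis can be exercised
and calibrated without any external data. Its defaults mirror the target
study design: 6 ROIs, 151 movie TRs and 180 rest TRs at TR = 2 s, traits
on 10-28, 7203 gaze frames at 24 fps on 1280 x 790, 768-dimensional
embeddings.

* **FC idiosyncrasy** is injected in Fisher-z space: subject FC is
  `tanh(template_z + sigma * E)` with `E` symmetric zero-diagonal
  standard Gaussian noise and `sigma = sigma0 + sigma1 * trait_norm` —
  the simplest monotone realization of the AnnaK premise. Defaults
  `sigma0 = 0.05`, `sigma1 = 0.2` put the top-of-range spread at five
  times the baseline, a large but not degenerate effect; `mode = "null"`
  forces the slope to zero. If the tanh-mapped matrix loses positive
  semi-definiteness it is repaired deterministically by clipping
  eigenvalues at 1e-6 and rescaling to unit diagonal. The template is
  compound-symmetric (r = 0.4) by default — of the right magnitude for
  within-network connectivity — and replaceable by any positive-definite
  correlation matrix.
* **Time series** are zero-mean Gaussian draws through the Cholesky
  factor of the subject's FC matrix, so the empirical correlation
  converges to it with length. There is no haemodynamic or autocorrelation
  model: inter-subject structure, not within-subject spectra, is what the
  downstream analysis consumes.
* **Gaze** is a shared deterministic Lissajous-style canonical path plus
  a smooth random deviation (sum of low-frequency sinusoids, unit SD,
  scaled by `sigma0_px + sigma1_px * trait_norm`), clipped to the frame,
  with single-frame dropouts, 2-5-frame blink runs and off-screen
  excursions inserted at configurable per-frame rates to exercise the
  preprocessing rules.
* **Embeddings** are drawn around a population direction `mu` by
  normalizing `kappa * mu + z` with `z` standard Gaussian and
  `kappa = kappa0 - kappa1 * trait_norm >= 0`: higher trait, lower
  concentration, higher expected cosine dissimilarity.
* **Traits and covariates** come from a Gaussian copula: a latent normal
  per subject is quantile-mapped to an integer-uniform trait (the
  distribution of real PT scores beyond their median split is not
  characterized, so uniform is the neutral choice and it is configurable),
  and each covariate is `rho * latent + sqrt(1 - rho^2) * noise` to hit a
  target trait correlation. Defaults include two genuine confounds
  (correlations 0.45 and 0.40, echoing the kind of empathy-adjacent
  scales that screen in) and one null covariate.
* **Seeding**: the master seed draws cohort-level quantities and one
  child seed per subject, so enlarging a cohort leaves existing subjects
  bit-identical.

What passing tests on these cohorts do **not** show: robustness to real
BOLD autocorrelation and motion artifacts, non-Gaussian gaze behavior
(saccade dynamics, fixation clustering), or the semantics of real
language — the generator makes the covariance structure the analysis
assumes, nothing more.

## Numerical and design choices

* Median-split ties go to the low group (`score > median` is high).
* Outlier exclusion uses |z| > 3 on subjects' mean dissimilarity.
* Edge vectorization order is row-major over the strict upper triangle;
  any fixed order gives identical Euclidean distances, but the order is
  documented so per-edge reports are stable.
* TR windows are 1-based and inclusive on both ends, so 1-50 / 51-110 /
  111-151 tile a 151-TR run exactly.
* The Mantel permutation count includes the identity (+1 convention).
* Degenerate inputs have defined behavior rather than NA surprises: a
  constant dependent variable returns zero contrasts with NA tests; zero
  spread across subjects disables outlier exclusion with a warning;
  collinear confounds are dropped with a warning; an all-invalid gaze
  trace and a sub-threshold dyad overlap are errors that name the
  offender.
* Simulation-based checks in the test suite use 20-30 subjects and a few
  hundred replicates, sizes at which the measured error rates and power
  (type-I about 0.07 at the df = N − k convention, power about 0.99
  against the default AnnaK effect) are stable run to run.

## Known limitations

* The df = N − k convention is liberal for small cohorts (see above);
  a subject-based effective-df approximation is deliberately not
  substituted because comparability of reported statistics was prioritized.
* The network-interaction F inherits the doubled-data optimism.
* `fit_dyad_gls` assumes a single homogeneous participant variance; no
  group-specific variances or random slopes are offered.
* Gaze dissimilarity is a global trajectory correlation; no fixation or
  scanpath events are modeled.
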