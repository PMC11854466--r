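---
title: "Methods: reproducibility scoring and group discrimination for brain morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reproducibility scoring and group discrimination for brain morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphorep)
```

# The setting

Regional brain volumes produced by automated segmentation (FreeSurfer's
`aseg` stream) are compared between IBS patients and healthy controls.
Because head size varies, absolute volumes (mm³) are divided by each
subject's estimated total intracranial volume (eTIV), giving dimensionless
ratios; `etiv_normalize()` performs exactly this division and leaves the
eTIV column itself untouched so it can still serve as a feature. Cognitive
performance enters as age-corrected RBANS index scores, scaled to mean 100
and SD 15 in the normative population. Symptom burden is the IBS-SSS score
(0–500; under 75 is minimal, 175 and above is the usual patient inclusion
threshold).

Two data granularities are supported, because replication work often has
only one of them:

* `cohort_summary` — per-region (n, mean, SD) for each group. Everything in
  the replication module works from these printed-table statistics alone.
* `subject_table` — one row per participant. Required by the multivariate,
  classification and simulation modules.

# Univariate effects

For a region with group summaries $(n_1, \bar x_1, s_1)$ (HC) and
$(n_2, \bar x_2, s_2)$ (IBS),

$$s_p = \sqrt{\frac{(n_1-1)s_1^2 + (n_2-1)s_2^2}{n_1+n_2-2}}, \qquad
  d = \frac{\bar x_1 - \bar x_2}{s_p},$$

with the 95% interval
$d \pm 1.96\sqrt{(n_1+n_2)/(n_1 n_2) + d^2/(2(n_1+n_2))}$. The sign
convention is fixed throughout the package: positive $d$ (and positive
Cliff's delta) means larger values in healthy controls. When $s_p = 0$ with
equal means, $d$ is 0 by convention; with unequal means it is an error, not
infinity.

Cliff's delta is the signed pair-probability
$\delta = (\#\{x_i > y_j\} - \#\{x_i < y_j\})/(n_x n_y)$, equivalently
$2U/(n_x n_y) - 1$ with ties counted 0.5 in the Mann–Whitney $U$. Only this
form attains $\pm 1$ exactly when the samples fully separate; the variant
$U/(n_x n_y) - 0.5$, which one sometimes encounters, spans only
$[-0.5, 0.5]$ and is not used. Two-sided p-values use exact enumeration for
tie-free samples with both groups of size at most 20 and the tie-corrected
normal approximation otherwise; at the 29/49 sizes this package targets,
the asymptotic branch is the operative one.

Strength bands follow the conventional closed intervals (Cliff: negligible
0.00–0.14, small 0.15–0.33, medium 0.34–0.47, large 0.48–1.00; Spearman:
negligible below 0.20, weak 0.20–0.39, moderate 0.40–0.59, strong
0.60–0.79, very strong 0.80–1.00). The printed band edges leave small gaps
(e.g. 0.475 for Cliff); values landing in a gap are assigned to the nearer
band, a choice that matters only at the third decimal.

# The reproducibility score

For one region measured in two analyses A and B (two cohorts, two software
versions, or two processing streams), the composite score is

$$S = \sigma + \omega + \epsilon$$

with $\sigma \in \{0,1\}$ for directional agreement,
$\omega \in \{0,1\}$ for 95% CI overlap (closed intervals — touching
endpoints overlap), and $\epsilon = \min(|d_A|, |d_B|)$. $S$ lives in
$[0,\, 2 + \epsilon]$ and is exchange-symmetric in A and B.
`concordance()` additionally reports the Pearson correlation between the
two effect-size vectors (Spearman available) and ranks regions by $S$,
breaking ties lexicographically so rankings are deterministic.

**Direction of a zero effect.** When $d$ is computed from a printed table
rounded to few decimals, exact zeros occur (several regions in the shipped
Bergen table have identical rounded group means). The default rule,
`zero_sign = "positive"`, takes the direction to be the boolean $d > 0$, so
zeros group with negative effects; this is also what naive sign-comparison
code produces on rounded inputs, which makes it the right default for
reproducing analyses performed that way. Two alternatives are available:
`"conservative"` (a zero paired with a nonzero effect never counts as
consistent — direction unconfirmed) and `"lenient"` (a zero is compatible
with either direction). On the shipped tables the three rules classify 19,
16 and 21 of the 35 regions as directionally consistent, respectively; the
choice affects only regions whose rounded effect is exactly zero and
leaves the score ranking's top end untouched, because those regions also
have $\epsilon = 0$.

A caveat worth stating explicitly: effect sizes recomputed from a
five-decimal summary table carry rounding error that is large relative to
group differences of order $10^{-5}$ in the normalized-volume scale, so
correlations between effect-size vectors are noticeably sensitive to that
rounding, while the maximum of $S$ and the top-ranked set are not.

# Multivariate separation

**Normality screening.** Mardia's multivariate skewness and kurtosis use
the definitional double-sum statistics with the maximum-likelihood
covariance and plain asymptotic reference distributions
($nb_{1,p}/6 \sim \chi^2_{p(p+1)(p+2)/6}$; standardized $b_{2,p}$ normal).
The Henze–Zirkler statistic uses the standard smoothing parameter
$b = ((2p+1)n/4)^{1/(p+4)}/\sqrt 2$ and the lognormal approximation for its
p-value. HZ is numerically fragile on near-collinear panels; singular
covariances and non-finite intermediates set an `unstable` flag on the
result instead of raising, so a pipeline can report the instability.

**Robust distance.** `robust_mahalanobis()` winsorizes each feature at the
10th/90th percentiles of the pooled sample (per-group winsorization is a
config option), takes per-group medians of the winsorized data as centers,
and pools the within-group covariance of the winsorized, group-centered
data with an $(n-2)$ denominator. Then
$D = \sqrt{(m_1 - m_2)^\top \Sigma^{-1} (m_1 - m_2)}$,
$T^2 = \frac{n_1 n_2}{n_1 + n_2} D^2$, and
$F = \frac{n_1 + n_2 - p - 1}{p\,(n_1 + n_2 - 2)} T^2$ on
$(p,\, n_1+n_2-p-1)$ degrees of freedom. Numerical choices:

* Percentiles interpolate linearly between order statistics (R's quantile
  type 7) — stated because percentile conventions differ across
  ecosystems, and winsorization limits are exactly reproducible only given
  the convention.
* With 35 features and 78 subjects the pooled covariance is
  near-singular, so a ridge $\lambda = 10^{-6}\,\mathrm{tr}(\Sigma)/p$ is
  added whenever the condition number exceeds $10^8$; the result records
  whether this triggered.
* $n_1 + n_2 \le p + 1$ is an error instructing feature reduction rather
  than a silent pseudo-inverse.
* Winsorization at (10, 90) on clean normal data shrinks the pooled SD by
  roughly 16%, inflating $D$ by the reciprocal factor. The robust $D$
  therefore agrees with the classical standardized mean difference only
  when clipping is disabled (`winsor_limits = c(0, 100)`), which is how
  the classical-oracle equivalence is tested. The robust default is meant
  for comparing like with like (both analyses robustified), not for
  absolute comparison against classical distances.

The F framing assumes normal-theory sampling of the winsorized data and is
reported as orientation, not as an exact test — which is precisely why a
permutation test accompanies it.

**Permutation test.** The statistic is the sum over features of squared
group-mean differences. Labels are reshuffled preserving group sizes
(default 1000 permutations, explicit seed), and the empirical p counts
permuted statistics **greater than or equal to** the observed one. A
strict "greater than" rule would report p = 0 on degenerate data (all
subjects identical) where p = 1 is correct; an optional
$(1+\#)/(1+n_{\mathrm{perm}})$ smoothing is provided for users who prefer
p-values bounded away from zero.

# Classification harness

The harness is classifier-agnostic: anything exposing `fit(x, y)` and
`predict_prob(model, x)` with probabilities in $[0,1]$ plugs in. The
shipped reference is a ridge-regularized logistic regression (glmnet,
$\alpha = 0$, fixed $\lambda = 0.1$ — deliberately not tuned, since the
harness, not the classifier, is the point); a gradient-boosted-trees
plug-in is provided behind an optional dependency.

Evaluation follows the stratified design: a 70/30 split preserving class
proportions within one subject (29/49 yields a 9 HC / 15 IBS test set),
mean imputation and standardization fitted on the training partition only,
and a 0.5 probability threshold with ties classified as IBS (the positive
class, coded 1). Cross-validation uses stratified folds with the same
inside-the-fold preprocessing and macro-averages the per-fold metrics; it
is plain (non-nested) k-fold, as no inner model-selection loop exists to
nest. All eleven confusion-matrix metrics plus Cohen's kappa are computed
from counts; ratios with zero denominators are `NaN` with a warning, never
silent zeros. AUC is computed by the Mann–Whitney rank identity, which
ties it algebraically to Cliff's delta
($\mathrm{AUC} = (\delta + 1)/2$) — a cross-module consistency the tests
exercise.

Permutation importance shuffles one feature column of the held-out data at
a time (default 10 repeats, seeded), recording the mean and SD of the
metric drop, ranked descending. On a test set of $m$ subjects,
count-based metrics move in steps of $1/m$; importance values below that
granularity are noise by construction.

# The synthetic cohort generator

`generate_cohort()` exists so that every stage is testable end to end
without subject-level data. Its defaults encode the study conditions
rather than convenient values, and were fixed once:

* 29 HC / 49 IBS; per-group means and SDs of the 35 normalized regional
  volumes equal to the shipped Bergen summary columns, so the generated
  group differences mirror the observed ones.
* Gaussian copula: regions are drawn from a multivariate normal with
  bilateral correlations 0.8 (hippocampus), 0.7 (amygdala), 0.9 (putamen)
  and a background inter-region correlation of 0.3, repaired to the
  nearest positive-definite matrix when user settings require it.
* Raw volumes are normalized volumes multiplied by a per-subject eTIV
  drawn from $N(1.5 \times 10^6, (1.2 \times 10^5)^2)$ mm³ clipped to the
  plausible adult range $[1.2, 1.8] \times 10^6$, so `etiv_normalize()`
  recovers the target scale exactly.
* Cognitive indices: multivariate normal, mean 100, SD 15, inter-index
  correlation 0.5, with IBS deficits of 0.45 SD on the full-scale and
  recall indices, 0.25 SD on memory/verbal/attention, and none on the
  visuospatial index — mirroring the direction and rough ordering of the
  reported group differences. Cross-correlation between cognitive indices
  and volumes is zero, consistent with the weak structure–function
  associations such cohorts show.
* IBS-SSS: truncated normals per clinical band — HC mean 25, SD 15 on
  $[0, 74]$; IBS mean 264, SD 71 on $[175, 500]$ — matching the reported
  medians and spread approximately (only medians and IQRs are available,
  so moments are matched, not quantile-for-quantile). Three scores per
  group are blanked; `impute_sss()` refills them by empirical draws within
  (group, sex) strata, which confines imputed values to the correct band
  automatically, with a group-only fallback for empty strata.
* Sex is assigned at female proportions 0.690 (HC) and 0.776 (IBS); age is
  normal around 34 (SD 10), truncated at 18.
* An `effect_vector` of true per-region Cohen's d values (HC minus IBS)
  overrides the two mean columns with an exactly injected effect
  (`mean_ibs = mean_hc - d * sd_hc`, equal SDs), for parameter-recovery
  and calibration experiments.

What the generator does **not** emulate: segmentation failures and
version-dependent biases (it draws from one well-behaved distribution, so
cross-pipeline comparisons on generated data are trivially concordant);
heavy tails and outliers (the robustness machinery is exercised on clean
data plus constructed contamination in tests, not on realistic artefact
distributions); any true structure–function coupling; and longitudinal
repeat structure. Passing tests on generated cohorts therefore validate
the statistical machinery, not claims about real MRI data.

# Determinism and problem sizes

Every stochastic function takes an explicit seed, runs under a local RNG
state (the caller's stream is never disturbed), and records the seed in
its result; `run_pipeline()` derives per-stage seeds from one master seed
and writes reports free of timestamps and absolute paths, so a repeated
run is byte-identical.

The test suite sizes its simulations to be decisive yet quick: 2,000
replicates for CI coverage at n = 100/group; 500 null datasets
(15 + 15 subjects, 3 features, 200 permutations each) for permutation-test
calibration; 200 replicates at n = 200/group for effect recovery; 200
draws at n = 500, p = 3 for Henze–Zirkler size; 20 constructed replicates
for importance ranking. These sizes give binomial standard errors
comfortably inside the asserted bands for the calibration checks.

# Known limitations

* The Hotelling-style F attached to the robust distance inherits the
  winsorization-induced scale change; treat its p-value as descriptive and
  prefer the permutation test for inference.
* Cliff's delta p-values for small tied samples fall back to the normal
  approximation; exact conditional enumeration under ties is not
  implemented.
* The reproducibility score treats the two analyses symmetrically and
  ignores estimation uncertainty in $\epsilon$; a region with two noisy
  but identical point estimates scores as high as one with two precise
  ones.
* Multiple imputation of severity scores is empirical-draw within strata
  (default m = 5); no between-imputation variance pooling is provided.
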