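---
title: "Multiblock discrimination analysis of untargeted metabolomics and lipidomics"
author: "omniblock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiblock discrimination analysis of untargeted metabolomics and lipidomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omniblock)
```

# Scope and model

`omniblock` analyzes feature-intensity tables from untargeted LC-MS
profiling of a two-group cohort: rows are injections (study samples,
pooled QCs, blanks), columns are annotated metabolite and lipid features.
The statistical question is whether, and through which biological
functions, the two groups differ. The workflow assumes:

* intensities are approximately log-normal after normalization;
* features belonging to the same biological function (or the same lipid
  cluster) share correlated variation;
* instrument response drifts smoothly with injection order and is
  observable through the interleaved pooled-QC injections;
* group effects are multiplicative (fold changes), common in direction
  within a function.

The package starts downstream of peak picking and annotation: raw spectra
processing, spectral matching and compound identification are out of
scope, as are more than two outcome classes.

# Preprocessing chain

The chain runs per assay (metabolomics and lipidomics columns separately,
because their QC and blank series come from different runs) in a fixed
order: blank removal, drift correction, CV filtering, PQN. Counts per step
are reported and can only decrease.

**Blank filtering.** A feature is kept iff mean(QC) >= `blank_ratio` x
mean(blank), boundary inclusive. The default ratio 3 is the conventional
signal-to-blank requirement in untargeted QA; it is configurable because
labs differ in carry-over tolerance. When all blank intensities of a
feature are zero, the comparison keeps it without any division.

**Drift correction.** Per feature, a LOESS curve (degree 1, tricube
weights, default `span` 0.75) of QC intensity versus injection order is
evaluated at every injection, clamping evaluation positions to the
observed QC range so extrapolation beyond the terminal QCs is constant.
Intensities are multiplied by median(QC)/fit. Because the pointwise ratio
does not exactly preserve the QC median, a final per-feature rescale pins
the post-correction QC median to its pre-correction value; the invariant
"drift correction never moves a QC median" is then exact. Features whose
fitted curve turns non-positive, or with fewer than 4 usable QC values,
are left uncorrected and flagged rather than corrupted.

**CV filter.** CV = sd/mean over QC rows; keep iff CV < `cv_cutoff`
(strictly, default 0.30 — a feature at exactly 30% is removed). Features
with fewer than two usable QC values are removed and counted separately.

**PQN.** The reference spectrum is the per-feature median over study rows;
each sample is divided by the median ratio of its spectrum to the
reference, over features positive in both. Dividing shifts the median
reference, so the quotient step is iterated to its fixed point (per-sample
Aitken-accelerated; convergence is geometric) and the accumulated quotient
is reported. At the fixed point a re-application returns quotients of 1,
i.e. the operation is idempotent — the plain one-pass version is not,
which matters when pipelines are re-entered.

**Scaling and outliers.** Multivariate models use column mean-centering
and unit-variance scaling by default (Pareto and centering-only are
available); univariate tests run on the normalized intensities with a log
transform, which makes the signed-fold-change convention symmetric.
PCA-based Hotelling T2 flagging (F-limit at the 0.99 quantile) is advisory
only: sample exclusion is an explicit user action, never automatic.

# Latent-variable core

PCA, PLS-DA and OPLS-DA are implemented as NIPALS iterations. PCA skips
missing cells, so it can inspect incomplete matrices; the supervised
models require complete data (the pipeline median-imputes any residual
missingness before modeling, and reports it). Convergence tolerance is
1e-12 on the score vector; component signs follow the
largest-|loading|-positive convention; ties in all clustering and ordering
operations break by input order, so results are reproducible to the byte.

The two-class response is a centered 0/1 dummy (PLS1). OPLS-DA removes
`n_orthogonal` components built from the loading-minus-weight projection
before fitting one predictive component; with `n_orthogonal = 0` it equals
PLS-DA with one component exactly, which the tests assert.

VIP uses the standard formula with unit-norm weights and per-component
explained response variance; mean(VIP^2) = 1 is checked as an algebraic
identity.

**Validation.** Q2 comes from stratified random folds (default 7),
re-centering and re-scaling inside each training fold. The permutation
test (default 200 relabelings) uses the add-one estimator
p = (1 + #{Q2_perm >= Q2_obs})/(n_perm + 1), so the smallest reportable p
is 1/(n_perm+1). CV-ANOVA is implemented as the PRESS-based approximation
F = ((SS - PRESS)/A)/(PRESS/(n - A - 1)); the exact residual bookkeeping
of the commercial implementation is not public, so this F is documented as
an approximation and tested for internal consistency instead.

# Multiblock analysis

Metabolites carry a curated functional block id; lipids are clustered by
Ward's method (`hclust`, `ward.D2`, Euclidean distance on scaled feature
profiles) into `n_lipid_clusters` blocks (default 11; a silhouette-style
automatic choice was considered and rejected to keep the block count an
explicit, reportable decision). Each block is compressed to the
standardized predictive score of a per-block OPLS-DA with one orthogonal
component (zero for blocks of fewer than 3 features; single-feature blocks
pass the scaled feature through, sign-aligned with the response). Scores
are weighted by sqrt(block size), normalized so the squared weights sum to
the number of blocks: a function summarizing more metabolites carries more
weight. The opposite (dominance-suppressing) convention is retained as
`inverse_sqrt_size` since both readings are defensible; the direction is a
genuine open choice and is recorded in every run's config.

**Honest validation of a supervised compression.** Composite scores are
built with knowledge of the labels, so cross-validating or permuting on
the fixed score matrix is circular and overstates Q2 badly on null data.
`hierarchical_cv()` and `hierarchical_permutation_test()` therefore
re-derive the entire compression — block models, signs, weights,
hierarchical fit — inside every training fold and every permutation. On
effect-free simulated cohorts this yields Q2 <= 0 and uniform permutation
p-values, which the test suite checks. The per-block t-tests on composite
scores retain the circularity of the published procedure by design; the
reported q-values for blocks should be read as descriptive ranking, with
the permutation p of the hierarchical model as the honest global
significance statement.

# Selection, network, enrichment

Features are selected by VIP > `vip_threshold` (default 1.0) together
with a two-sided test (default Welch t on log intensities; Student,
paired, and Mann-Whitney variants are available since the matched design
admits either analysis). Raw p is the default selection criterion at
feature level, with Benjamini-Yekutieli q-values always attached; block-
and family-level claims use the adjusted values. B-Y rather than B-H
because the tests are arbitrarily dependent. Signed fold changes report r
when case/control >= 1 and -1/r otherwise, so magnitudes are always >= 1
and antisymmetric under group exchange.

The block network uses shrinkage partial correlations: the correlation
matrix of block scores is shrunk toward the identity with the analytic
variance-minimizing intensity (clamped to [0, 1]), which keeps the
estimate positive definite even with more blocks than samples, then
inverted and rescaled. Edge p-values use a t-approximation with
df = n - G when positive and a Fisher-z normal approximation otherwise;
this replaces the empirical-null mixture modeling of the package
tradition in this area with something simpler and directly testable. The
default edge threshold p <= 0.25 deliberately reproduces the permissive
"initial network" convention; tighten `network_p_threshold` for
confirmatory views. Betweenness centrality is computed on the unweighted
thresholded graph (no edge-weighting rule is imposed on centrality).

Enrichment is a hypergeometric over-representation test. The universe is
the set of annotated metabolites that survived preprocessing — not the
whole catalog — to avoid inflating significance with compounds that were
never measurable. Enrichment q-values use Benjamini-Hochberg (the B-Y
choice above concerns the omics feature tests; pathway tests are fewer
and the convention in enrichment tools is B-H). Name matching is
case-insensitive and whitespace-normalized, never fuzzy.

# The synthetic cohort generator

`generate_table()` draws, per feature, a baseline log-intensity, a target
QC CV (uniform on 10-40% by default, straddling the 30% filter) that sets
the log-scale noise sigma = sqrt(log(1 + CV^2)), and a block-shared latent
factor whose loading produces a chosen within-block correlation (default
0.5). Half of the blocks (default) carry a group effect: a per-block sign
and per-feature fold-change magnitudes drawn between 1.05 and 1.9.
Injection order is randomized with a pooled-QC injection after every 4th
study sample and blank injections at the head of the run; a smooth
per-feature sinusoid of random phase and frequency multiplies intensities
by 1 +/- 20% to emulate drift; QC rows draw at the pooled mean with
analytical noise only; blanks sit near 1/20 of the median baseline.
Ground truth (affected blocks and features, signed fold changes, cluster
memberships, drift parameters, target CVs) is returned alongside.

What the generator does **not** emulate: missing-not-at-random dropout at
low intensity, retention-time-correlated artifacts, adduct/isotope
redundancy between features, batch structure across multiple series, and
heavy-tailed contamination. Passing recovery tests on this generator
therefore demonstrates the statistical machinery under the model's
assumptions, not robustness to every pathology of real acquisitions.

Defaults mirror the cohort scale the pipeline targets (97 samples per
group, 228 metabolite and 335 lipid features, 54 functional blocks, 11
lipid clusters, 1-in-5 QC injections). `missing_rate` defaults to 0
because annotated-feature tables are typically near-complete by the time
they reach statistics; it is tunable. Blank count defaults to 5.

# Numerical choices and degenerate inputs

* NIPALS tolerance 1e-12, capped iterations with an explicit error naming
  the component on non-convergence.
* Zero-variance columns are dropped with a warning before scaling.
* Fold assignment is stratified and seed-controlled; a fold that loses a
  class triggers refolding (up to 10 attempts) before erroring.
* Blocks whose OPLS-DA fails fall back to 0 orthogonal components, then
  are dropped with a warning and recorded.
* All randomized operations take explicit seeds; `run_all()` derives
  per-stage seeds from the config seed and writes the resolved config, so
  identical seeds give byte-identical CSV outputs.
* Test-suite problem sizes: unit tests run on cohorts of 30-150 samples
  per group and tens of features; calibration suites use 60 x 40 null
  matrices with 99 permutations over 200 datasets; recovery suites run 20
  seeds at the full default cohort scale. These sizes were chosen so the
  statistical assertions have the power they claim while the whole suite
  stays comfortably runnable on a laptop core.

# Known limitations

* Two classes only; multi-class designs need a different response coding.
* The block t-tests inherit the circularity of testing supervised
  composite scores (see above); interpret block q-values as ranking.
* The CV-ANOVA is a PRESS-based approximation, not the proprietary
  variant.
* Weak planted effects (fold changes near 1.1 on noisy features) are not
  reliably separable from supervised-overfitting noise at block level;
  the ranking of affected blocks is excellent on average (AUC near 1 in
  simulations) but strict separation of every affected block above every
  null block should not be expected at realistic effect sizes.
* Partial-correlation edge p-values are approximations under shrinkage;
  support recovery, not exact error control, is the tested guarantee.
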