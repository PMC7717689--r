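---
title: "Hierarchical differential expression for multi-region brain cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical differential expression for multi-region brain cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hierde)
```

## The problem

Post-mortem brain expression studies often sample several regions from each
donor. Samples from the same subject are correlated, so treating them as
independent replicates understates the uncertainty of any case/control
contrast and inflates the type-I error — the more regions per subject, the
worse the inflation. `hierde` implements a differential-expression pipeline
for exactly this design: per-gene linear mixed models with a subject random
intercept, precision weights derived from a LOWESS mean–variance trend,
empirical-Bayes moderation of the gene-wise variances, and Bonferroni
control, followed by enrichment analyses and an exhaustive gene-panel
classification protocol with subject-disjoint evaluation.

## The model

For gene $g$ and sample $i$ with log2 expression $y_{gi}$ (FPKM + 1,
log2-transformed, adjusted for age and sex),

$$y_{gi} = \beta_{0g} + \beta_{1g}\,\mathrm{AD}_i + u_{g,\,subj(i)} +
\varepsilon_{gi}, \qquad
u \sim N(0, \tau_g^2), \quad
\varepsilon_{gi} \sim N(0, \sigma_g^2 / w_{gi}),$$

where $\beta_{1g}$ is the log2 fold change of AD over control and $w_{gi}$
are per-observation precision weights. The model is estimated by REML with
the variance ratio $\theta = \tau^2/\sigma^2$ profiled out numerically
(compiled code; the single-random-intercept structure admits closed-form
block inverses, so each evaluation is linear in the number of samples). At
$\theta = 0$ the fit reduces exactly to weighted least squares; estimates
agree with `lme4::lmer` to the optimizer tolerance, which the test suite
verifies.

**Weights.** An unweighted per-gene OLS first pass (same fixed effects,
subjects pooled) yields the average log2 expression and the square root of
the residual standard deviation per gene. A robust LOWESS smoother (span
0.5, 3 robustness iterations, both configurable) of sqrt-sd on mean
expression predicts, at each observation's fitted value, the expected
sqrt-sd; the precision weight is the inverse predicted variance,
$w = \widehat{\mathrm{sd}}^{-4}$. Weights are computed after covariate
adjustment, on the log scale, so they reflect the residual variance of the
model actually fitted. Genes with degenerate first-pass fits (zero residual
variance) receive weight 1 and a QC flag.

**Moderation.** Gene-wise variances $s_g^2$ are squeezed toward a common
prior, $\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$, with
$(d_0, s_0^2)$ estimated by matching the first two moments of $\log s_g^2$
through digamma/trigamma identities (a degenerate spread yields
$d_0 = \infty$, i.e. complete shrinkage). The moderated t-statistic is
$\tilde t_g = \hat\beta_{1g} / (\tilde s_g \cdot u_g)$ with $u_g$ the
unscaled standard error, referenced against a Student-t distribution with
$d_0 + d_g$ degrees of freedom. The B-statistic reports the posterior
log-odds of differential expression under a two-component prior
(proportion 0.01 by default; the prior variance of the non-null effects is
estimated from the upper tail of the moderated statistics).

## Degrees of freedom: a deliberate choice

The disease contrast is a *between-subject* comparison: its information is
governed by the number of subjects, not the number of samples. Attaching
the full residual degrees of freedom ($n_{samples} - p - 1$) to the
moderated t makes the reference distribution too light-tailed far out in
the tail — in our null simulations the pointwise rejection rate at 0.05
looks acceptable, but the Bonferroni family-wise error rate is inflated
several-fold, exactly where a genome-wide Bonferroni gate operates. The
default is therefore a between-within convention,
$d_g = n_{subjects} - p_{between}$, where $p_{between}$ counts the fixed
effects constant within subject (intercept and diagnosis; region dummies
vary within subject and do not count). `fit_all(..., df_method =
"residual")` restores the sample-based convention for comparison. Under
the default, 20 null cohorts of 2,000 genes give a raw rejection rate of
about 0.05 and a family-wise error rate consistent with the nominal 0.05,
which the acceptance suite checks.

## What the synthetic cohorts emulate

`cohort_design()` and `simulation_params()` encode the study conditions the
pipeline is validated under: 15 AD and 30 control subjects; four brain
regions (HIP, TCx, PCx, FWM) per subject; a per-(subject, region)
missingness probability of 0.083, tuned so the expected retained sample
count is about 165 of 180 (the missingness mechanism is uniform at random —
a modeling assumption, since nothing stronger is known); age at death
normal with mean 88 and sd 6 years, truncated at 60; 44% female; APOE e4
carrier rates of 1/3 (AD) and 10% (control).

On the log2 scale, expression is baseline + planted disease effect +
per-(gene, region) shift + age and sex effects + subject random intercept +
heteroskedastic noise. Defaults: 2,000 genes (the genome-wide 50,281 is a
configuration value, not a default — it changes nothing but runtime);
subject sd $\tau = 0.5$; region-shift sd 0.5; age slope 0.01 log2/year; sex
shift 0.1; mean–variance trend $\mathrm{sd}(\mu) = 0.2 + 1.5 e^{-0.4\mu}$
(decreasing and strictly positive, mimicking RNA-seq-like
heteroskedasticity); 1.2% of genes differentially expressed with |log2
effect| 0.6, 80% of them upregulated in AD — mirroring the predominance of
upregulation reported in multi-region AD analyses. Baselines are drawn from
$N(5, 1.5^2)$, i.e. expressed genes: with this choice the floor at zero
FPKM (the matrix is emitted as $2^{signal} - 1$, clipped at 0) is rarely
active and the generative structure survives the FPKM round trip.

What the generator does *not* emulate: zero-inflated barely-expressed
genes, count noise, library-size artifacts, correlated gene modules,
region-specific disease effects, or Braak-stage progression. Passing tests
therefore demonstrate correctness of the statistical machinery under the
assumed hierarchical Gaussian model, not robustness to every pathology of
real RNA-seq data.

## Preprocessing order

The pipeline defaults to log-transform first (offset 1), then adjust for
age and sex by per-gene OLS, returning residuals plus the gene grand mean
(average expression is preserved and the adjusted values are exactly
orthogonal to the covariates; the operation is idempotent). The literal
adjust-then-log order is available (`preprocess.order =
"adjust_then_log"`), but OLS residuals of raw FPKM can be negative and have
no logarithm; that mode restores the gene grand mean and floors at a small
positive value before the log, with a logged warning. The default order is
the numerically well-defined one. Adjusting out `diagnosis` is refused —
that would remove the effect of interest.

## Enrichment

Over-representation uses the exact hypergeometric upper tail with
Bonferroni correction over the number of sets; the universe defaults to
all genes in the expression matrix, not the annotation's universe. Gene
IDs are matched as exact case-sensitive strings throughout; no ID
translation is attempted. Pre-ranked GSEA ranks genes by the signed
moderated t (ties broken by gene ID for determinism) and uses the weighted
running-sum statistic (exponent 1 by default; 0 gives the classic
Kolmogorov–Smirnov form used in unit tests). Significance is by gene-set
permutation — size-matched random sets drawn from the ranked list — since
phenotype permutation is unavailable for a pre-ranked metric. NES divides
ES by the mean magnitude of same-sign null scores; the permutation p-value
is add-one smoothed; FDR follows the usual pooled-null convention.
Similarity coefficients for enrichment-map edges are reported as Jaccard,
overlap and their equal-weight combination.

## Classification protocol

The top 10 genes by corrected p-value are candidate features. Subjects —
never samples — are randomly assigned to train/test, stratified by
diagnosis, choosing per-group counts so the training sample count is as
close as possible to 70% of all samples; subject-level assignment
quantizes sample counts, so the target is met only approximately. For each
panel size $N$ from 2 to 10, all $\binom{10}{N}$ combinations (1,013 in
total) are scored by training accuracy only; the winner (ties broken by
lexicographic order) is then evaluated once on the test set. Test labels
cannot influence selection, which the suite verifies by a shuffle test.
Four classifiers are searched: linear SVM (C = 1), RBF SVM (C = 1, gamma =
1/(N · mean feature variance) on standardized features), random forest
(500 trees, seeded), and a quadratic Bayes classifier implemented as
quadratic discriminant analysis with covariance regularization $10^{-3}$
(needed for small panels). Features are standardized with training-set
statistics only. No resampling is applied to the class imbalance. The
reported generalization bound is the Hoeffding bound
$\epsilon = \sqrt{\ln(2/\delta)/(2 n_{test})}$ at $\delta = 0.5$, with
out-of-sample error $\le$ test error $+ \epsilon$.

## Numerical choices and degenerate inputs

* REML profile search: coarse log-spaced grid on $\theta \in [0, 50]$
  followed by golden-section refinement; the boundary $\theta = 0$ is
  always compared explicitly, so the weighted-least-squares limit is exact.
* Per-gene weights are normalized to mean 1, making fits invariant to
  rescaling a gene's weights.
* Constant genes are flagged (`converged = FALSE`), keep NA statistics,
  and still count toward the Bonferroni denominator — genes are never
  silently dropped.
* The LOWESS trend clamps to its boundary value outside the fitted range
  and is floored at $10^{-6}$ so weights stay finite.
* Wilcoxon region tests use the exact distribution when the combined
  sample size is at most 20 (and ties are absent), otherwise the normal
  approximation with tie correction; fully tied data reports p = 1.
* All stochastic stages (simulation, GSEA permutation, splits, random
  forest) are driven by explicit seeds; identical configuration and seed
  reproduce outputs byte-identically.

## Problem sizes used in validation

The test and acceptance suites run at what we consider desk scale for this
design: cohorts of 45 subjects and roughly 165 samples; 2,000 genes for
calibration batches (20 null replicates), 1,500 genes for effect-recovery
batches (500 planted genes per effect size), 5,000 genes for
variance-prior recovery, 1,000 permutations for GSEA detection checks and
200 for calibration checks. These sizes give Monte-Carlo error comfortably
inside the asserted tolerances while keeping a full run in minutes.

## Known limitations

* A single random intercept per subject; random slopes or crossed effects
  are out of scope.
* The moderated-t degrees of freedom use the between-within convention
  rather than a per-gene Satterthwaite approximation; the latter would
  adapt to unbalanced missingness at additional cost.
* FDR-based gene selection is not implemented — the DE gate is Bonferroni
  by design.
* ORA treats annotation sets as flat gene lists; ontology hierarchy and
  term propagation are not implemented.
* The FPKM floor mildly censors genes whose baseline is near zero; at the
  default baseline distribution this affects a negligible fraction of
  values.
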