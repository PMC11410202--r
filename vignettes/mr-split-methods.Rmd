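---
title: "MR-SPLIT: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MR-SPLIT: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrsplit)
```

## The problem

One-sample Mendelian randomization (MR) estimates the causal effect of an
exposure $X$ on an outcome $Y$ using SNPs as instrumental variables, from a
single cohort with individual-level data.  The working structural model is

$$Y = X\beta + \varepsilon_y, \qquad X = G\alpha + \varepsilon_x,$$

with $G$ an $N \times p$ additive dosage matrix and
$(\varepsilon_x, \varepsilon_y)$ jointly normal with correlation $\rho$ — the
unmeasured confounding that makes the naive regression of $Y$ on $X$
uninterpretable causally.

Two finite-sample biases plague the standard two-stage least squares (2SLS)
analysis of such data:

* **Weak-instrument bias.**  With many instruments of small effect, the
  first-stage fitted values overfit, and the 2SLS estimate is pulled toward
  the confounded association, inflating type-I error.
* **Winner's curse (IV selection bias).**  Selecting instruments and
  estimating the causal effect on the *same* sample biases the first stage
  toward the sample's noise, again distorting the estimate.

This package implements an estimator that addresses both through one device:
an adaptive 2-fold sample split with cross-fitted instruments, aggregated
over many random splits.

## The estimator

For each random split $\{I_1, I_2\}$ with $|I_1| = \lfloor N/2 \rfloor$:

1. **Selection on the complement.**  For each half $I_k$, instruments are
   selected on $I_k^c$: sure independence screening (SIS) ranks SNPs by
   absolute marginal correlation with the exposure and keeps the top
   $\lfloor n_{\text{train}}/2 \rfloor$; a cross-validated LASSO (or,
   optionally, a desparsified LASSO with a p-value threshold) then picks the
   working instrument set and its effect estimates $\hat\alpha$.
2. **Major/weak classification.**  Each selected instrument's strength is
   measured by its partial F statistic in the joint first-stage regression,
   $F = \{(\mathrm{RSS}_r - \mathrm{RSS}_f)/1\} / \{\mathrm{RSS}_f/(n-k-1)\}$.
   Instruments with $F > 30$ (configurable) are *major* and enter the first
   stage individually; the rest are *weak*.
3. **Composite instrument.**  The weak instruments are consolidated on $I_k$
   into one composite dosage
   $\hat G_{k,W} = \sum_j \omega_j G_{k,j}$ with sign-preserving,
   L1-normalized weights $\omega_j = \hat\alpha_j / \sum_j |\hat\alpha_j|$
   estimated on $I_k^c$.  Because the weights come from the opposite half,
   the composite does not overfit the half it is evaluated on.
4. **Cross-fitted exposures and second stage.**  OLS of the exposure on
   (intercept, majors, composite) within each half gives fitted values
   $\hat X_k$; stacking them in the original sample order gives $\hat X$,
   and the causal estimate is the coefficient of $\hat X$ in the second-stage
   regression of $Y$ on $(1, \hat X)$ over the full sample,
   $\hat\beta = (\hat X'\hat X)^{-1} \hat X' Y$ after centering.

Across $L$ random splits, the per-split p-values are aggregated with the
Cauchy combination rule
$T = \sum_l \omega_l \tan\{(0.5 - p_l)\pi\}$, $p = 1/2 - \arctan(T)/\pi$,
with equal weights $\omega_l = 1/L$, and the aggregated estimate is the mean
of the per-split estimates.  The Cauchy rule is valid under arbitrary
dependence between the splits, which share the same data.

```{r example}
sim <- simulate_dataset(sim_config(
  n = 800, p_snps = 100, h2 = 0.4, rho = 0.2, beta = 0.15, seed = 42
))
fit <- mr_split(sim$data, n_splits = 10, master_seed = 42)
fit
```

## Comparators

* `tsls_full()` — plain 2SLS with every selected instrument entering
  individually; the benchmark that suffers weak-instrument bias.
* `liml()` — limited-information maximum likelihood, the k-class estimator
  with $\kappa$ set to the smallest eigenvalue of the usual eigenproblem on
  centered data; less biased under weak instruments, larger variance, and
  defined only for continuous outcomes.
* `cfmr()` — cross-fitted MR: a K-fold cross-fitted polygenic-score-like
  instrument (the fold's exposure prediction from a model trained on the
  complement), then just-identified 2SLS.  At a matched 2-fold split,
  MR-SPLIT's estimate is at least as efficient — the package's simulation
  tests check this variance dominance empirically.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `n_splits` (`L`) | 50 | random splits aggregated; power typically stabilizes by 50, earlier for large N or strong instruments |
| `f_threshold` | 30 | partial-F cutoff for major instruments; 10 is lenient (noise SNPs slip through at small N), 50 stringent (misses true signals at low heritability) |
| `keep` | half the training sample | SIS retention count |
| `selector` | `"lasso"` | `"lasso"` (CV-min penalized coefficients as $\hat\alpha$) or `"dlasso"` (desparsified LASSO, retain $p \le 0.05$, debiased $\hat\alpha$) |
| `refit_alpha` | `FALSE` | replace selector coefficients by a post-selection OLS refit |
| `min_success` | 10 (capped at `L`) | minimum successful splits before the aggregate errors out |

## Design choices

Points the method statement leaves open were settled as follows.

* **Intercepts everywhere.**  All selection, partial-F, first- and
  second-stage regressions include an intercept, which makes the partial F
  scale- and location-free and keeps the estimator applicable to uncentered
  real data.
* **Partial-F degrees of freedom.**  The denominator uses the classical
  convention $n - k - 1$ with $k$ the *full*-model predictor count, under
  which the partial F of a lone instrument equals the squared t statistic of
  its simple-regression slope.
* **Composite weights from the penalized fit.**  $\hat\alpha$ is taken
  directly from the selector (LASSO coefficients, or debiased estimates under
  `"dlasso"`); a post-selection OLS refit is available behind `refit_alpha`.
  Weights keep their signs; magnitude-only weights would mis-cancel
  opposite-signed instruments.
* **LASSO penalty at the CV minimum** with 5-fold cross-validation and a
  seeded fold assignment.  Selection feeds estimation on independent data, so
  mild over-selection is tolerable — extra weak instruments are absorbed into
  the composite.  Note that comparator behavior is sensitive to this choice:
  the more liberally instruments are selected, the stronger plain 2SLS's
  weak-instrument bias; a CV-min LASSO keeps the instrument count modest, so
  2SLS looks better here than under a more permissive rule.
* **2SLS standard error** uses the conventional econometric formula: the
  error variance is estimated from residuals formed with the *observed*
  exposure, $Y - \hat a - X\hat\beta$, and p-values/CIs use the t
  distribution with $n - 2$ degrees of freedom.
* **Binary outcomes** use logistic second-stage predictor substitution
  (so $\exp(\hat\beta)$ is an odds ratio); LIML refuses binary outcomes.
* **Failed splits.**  A half with an empty selection fails the whole split;
  failed splits are excluded and the Cauchy weights renormalized over the
  successful ones, with attrition reported.  Re-drawing splits silently would
  bias the aggregate toward datasets that happen to select instruments.
* **Seeding.**  Every stochastic step (split membership, CV folds, fold
  assignment in CFMR, simulation draws) derives its seed from one master
  seed via seeded streams, so any single split or replicate can be re-run in
  isolation and whole studies are bit-reproducible.
* **Degenerate inputs.**  Zero-variance SNPs are screened out with a
  warning; collinear first-stage columns are dropped with a warning;
  p-values of exactly 0 or 1 are clamped before the Cauchy transform; a
  constant fitted exposure or composite is a hard error (no identification).

## The synthetic-data generator

`simulate_dataset()` draws independent SNPs with entries
$\mathrm{Bin}(2, \mathrm{MAF})$ at a common MAF (default 0.3), gives $k$
causal SNPs effects $\alpha = \omega_0 a$ for a base pattern $a$ (default
$(0.4, 0.4, 0.1, 0.05, 0.05)$ — two strong, three weak instruments), and
scales $\omega_0$ so the causal SNPs explain exactly a target fraction $h^2$
of the exposure variance:
$\omega_0 = \sqrt{h^2 \sigma^2 / \{(1-h^2)\, \textstyle\sum_j a_j^2 \cdot 2\,
\mathrm{MAF}(1-\mathrm{MAF})\}}$.
Errors are bivariate normal with common variance $\sigma^2$ and correlation
$\rho$.  The generator emulates the idealized conditions under which the
estimator's properties are cleanest: no linkage disequilibrium, no
pleiotropy, exact additive coding, homoskedastic normal errors.  Passing
tests on these data therefore demonstrate the estimator's behavior under its
own assumptions; they do not establish robustness to LD-correlated
instruments, pleiotropic pathways, or non-normal confounding, all of which
real cohorts exhibit.

## Study sizes and what the checks show

The acceptance-style tests reproduce the method's headline phenomena at desk
scale on one CPU: estimator-comparison cells use 150 replicates
(300 in `scripts/acceptance.R`), the identification study 100–200, the
variance-dominance study 100, and the split-count study 15 replicates of an
80-split run.  All probabilistic assertions carry Monte-Carlo tolerance
bands of three standard errors at the realized replicate count, so smaller
studies get proportionally wider bands rather than silently weaker checks.

## Known limitations

* Only 2-fold splitting is implemented for MR-SPLIT (the balance between
  selection and estimation data argues for halves; CFMR keeps its usual
  K-fold).
* No covariate adjustment, no GWAS-summary-statistic (two-sample) interface,
  no genotype QC — inputs are assumed PLINK-cleaned, and PLINK binary files
  must be recoded to dosage text first.
* No pleiotropy handling or robust-MR variants.
* The multi-split aggregate reports an estimate and a combined p-value but
  no aggregated confidence interval; per-split CIs are retained instead.
* Heteroskedasticity-robust standard errors are not offered.
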