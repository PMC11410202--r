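# mrsplit

One-sample Mendelian randomization (MR) with adaptive sample splitting and
cross-fitted instruments.

## The problem

MR estimates the causal effect of an exposure on an outcome by using genetic
variants as instrumental variables.  With individual-level data from a single
cohort, the standard two-stage least squares (2SLS) analysis faces two
finite-sample biases at once:

* **weak-instrument bias** — many small-effect SNPs overfit the first stage
  and pull the estimate toward the confounded association, inflating false
  positives; and
* **the winner's curse** — selecting instruments and estimating the causal
  effect on the same sample biases the selected effects away from zero.

`mrsplit` implements an estimator that attacks both with one device.  Under
the structural model

```
Y = X beta + e_y,    X = G alpha + e_x,    cor(e_x, e_y) = rho,
```

each random 2-fold split `{I1, I2}` selects instruments on one half (SIS
screening + cross-validated LASSO, or a desparsified LASSO), classifies them
into **major** (partial F > 30) and **weak** instruments, consolidates the
weak ones into a sign-preserving composite dosage on the *opposite* half with
L1-normalized weights `w_j = alpha_j / sum(|alpha_j|)`, fits the first stage
within each half, stacks the cross-fitted exposures `Xhat`, and estimates
`beta_hat = (Xhat' Xhat)^(-1) Xhat' Y`.  P-values from `L` random splits are
aggregated with the Cauchy combination rule

```
T = sum_l (1/L) tan((0.5 - p_l) pi),    p = 1/2 - arctan(T) / pi,
```

and the reported estimate is the mean of the per-split estimates.
Comparators 2SLS (`tsls_full`), LIML (`liml`) and cross-fitted MR with a
single polygenic-score instrument (`cfmr`) are included, along with a full
Monte-Carlo harness for bias, coverage, type-I error and power studies.

## Worked example

```r
library(mrsplit)

# synthetic cohort: 800 samples, 100 independent SNPs, 5 causal SNPs
# explaining h2 = 0.4 of the exposure, confounding rho = 0.2, beta = 0.15
sim <- simulate_dataset(sim_config(
  n = 800, p_snps = 100, h2 = 0.4, rho = 0.2, beta = 0.15, seed = 42
))

fit <- mr_split(sim$data, n_splits = 10, master_seed = 42)
fit
#> <multisplit_result> L=10 splits (10 ok, 0 failed)
#>   aggregated beta = 0.1780, Cauchy-combined p = 7.17e-06

head(as.data.frame(fit), 3)
#>   split estimate     se     pval n_major n_weak status
#> 1     1    0.186 0.0400 3.83e-06       2    5.5     ok
#> 2     2    0.179 0.0401 9.02e-06       2   13.0     ok
#> 3     3    0.185 0.0396 3.68e-06       2   15.0     ok
```

The aggregated estimate 0.178 recovers the true effect 0.15 to within its
per-split standard error (~0.04) despite the confounding; `n_major`/`n_weak`
show how many instruments each half classified as major (kept individually)
versus weak (merged into the composite).  Real data enter through
`read_mrdata(genotypes.tsv, phenotypes.tsv, exposure, outcome)` — a delimited
dosage matrix (samples x SNPs, additive 0/1/2 coding; recode PLINK binaries
with `plink --recode A`) plus a phenotype table joined on sample id.

A command-line wrapper is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/mrsplit.R", package = "mrsplit"))') \
  run --geno G.tsv --pheno P.tsv --exposure bmi --outcome chd \
      --splits 50 --f-threshold 30 --selector lasso --seed 1 --out results.tsv
```

with `simulate` and `compare` subcommands driving the simulation harness from
YAML configs.

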