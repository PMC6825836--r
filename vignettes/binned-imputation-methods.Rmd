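---
title: "Binned multiple imputation for EWAS with missing covariates: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binned multiple imputation for EWAS with missing covariates: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

An epigenome-wide association study (EWAS) fits one small regression per
CpG site — here `CpG ~ age + sex + smoking` — across hundreds of thousands
of sites. When a covariate such as smoking status is partly missing, the
common fallback is a complete-case (C-C) analysis, which discards
individuals and with them statistical power. Multiple imputation (MI) is
the standard remedy, but it has a high-dimensional complication: to avoid
biasing an association towards the null, the imputation model for the
covariate must contain the outcome of the analysis model — and in an EWAS
*every site* is an outcome. Imputing smoking from all ~480,000 sites at
once is impossible with a few hundred cases, so the question becomes: which
sites go into which imputation model?

`binmi` implements and compares the candidate answers as six strategies:

* **complete_case** — no imputation; the baseline.
* **separate** — one imputation procedure per site (`smoking ~ site + age +
  sex`); statistically clean and computationally extreme.
* **random_bins** — partition the sites into random bins of fixed size
  `b`; impute once per bin from `smoking ~ b sites + age + sex`, and use
  that bin's imputations for the EWAS of exactly the sites in the bin.
  With `N` sites this costs `ceiling(N / b)` imputation procedures.
* **naive** — one imputation model containing every site that was
  Bonferroni-significant in the C-C analysis.
* **wu** — one imputation model containing a forward-stepwise BIC
  selection from the top 100 C-C-ranked sites.
* **wu_bins** — random bins with the Wu selection added to every bin;
  `ceiling((N - s) / (b - s))` bins for a selection of size `s`.

The known trade-off that the simulation harness measures: the selection
strategies (naive, wu) concentrate information and gain power, but any
*true* site left out of the imputation model has its association attenuated
towards the null; the partition strategies (separate, random bins, wu bins)
give every site a seat in some imputation model and stay unbiased, at
varying computational cost and efficiency.

## Analysis model and pooling

Each site's methylation vector is standardized (mean 0, sample SD 1 with
denominator `n - 1`, so a `[1, 2, 3]` row maps exactly to `[-1, 0, 1]`);
coefficients are therefore in per-site SD units. The EWAS model is
ordinary least squares with female and never-smoker as reference levels,
age in years uncentred, and two-sided t p-values. A site counts as
associated with smoking when the smaller of its two smoking p-values
(former, current) falls below the Bonferroni threshold `alpha / N` — the
"either coefficient" reading. A 2-df joint F test is available as an
alternative (`run_ewas(smoking_test = "joint-F")`) for single-dataset fits;
it is not offered on pooled MI output, where a joint test would require
multivariate pooling of the coefficient covariance across imputations,
beyond what the strategy comparison needs.

Per-imputation fits are pooled by Rubin's rules: pooled estimate
$\bar q = \frac1m \sum_i \hat q_i$, within-variance $W = \frac1m \sum_i
\widehat{se}_i^2$, between-variance $B = \frac{1}{m-1}\sum_i (\hat q_i -
\bar q)^2$, total $T = W + (1 + 1/m)B$. Degrees of freedom use the
Barnard–Rubin small-sample formula with the complete-data residual df —
material here, where a cohort of a few hundred meets `m` of 10–100. When
`B = 0` (nothing was imputed, or all imputations agree) the pooled result
degenerates by convention to the single fit with the complete-data df.

## The imputation engine

Smoking is a three-level factor, imputed by polytomous (multinomial)
logistic regression: fit `smoking ~ age + sex + bin sites` on the complete
cases, then draw each missing case's category from its fitted
probabilities. The fitter is a Newton–Raphson solver (RcppArmadillo) with
a ridge penalty (default `1e-5`) on the non-intercept coefficients: with
up to 150 standardized, near-collinear sites on ~360 complete cases,
unpenalized fits court separation, and the small ridge keeps coefficients
finite without noticeably shrinking the probabilities. Iterations are
capped (30) with step-halving, so a near-separated fit returns its current
(finite) solution rather than diverging — the same pragmatic behaviour as
the iteration caps in standard multinomial fitters. The solver is
cross-checked against `nnet::multinom` in the test suite.

Two variants of parameter uncertainty are provided:

* `impute_polytomous(boot = TRUE)` (its default) refits the model on a
  bootstrap resample of the complete cases for every imputation — proper
  MI, with parameter uncertainty propagated into the between-imputation
  variance. Resamples that lose an observed category are redrawn (at most
  10 times).
* `run_strategy()` defaults to `boot = FALSE`: one fit per bin, all `m`
  imputations drawn from the fitted probabilities. This mirrors the
  behaviour of the polytomous-regression imputation routine in the
  standard MI software that the binning strategies were originally
  evaluated with, and it is what reproduces the published efficiency
  ordering: with bootstrap draws at `m = 20`, the extra between-imputation
  variance pushes the separate-sites strategy's mean pooled SE slightly
  *above* the complete-case SE, inverting the expected ranking. Users who
  prefer proper draws can set `boot = TRUE` and should expect slightly
  larger pooled SEs.

If only one smoking category is observed, imputation fills that category
deterministically. An imputation model with as many predictors as complete
cases is refused with advice to use smaller bins.

For multi-covariate missingness (the applied-cohort situation), chained
equations are provided: initialize missing cells from observed marginals,
then cycle over incomplete variables in order of increasing missingness,
re-imputing each from the current completed values of its predictors, for
`n_cycles = 10` cycles (deliberately above the common default of 5, since
the visit order and cycle count are otherwise unconstrained here), repeated
independently `m` times. Continuous auxiliaries use predictive mean
matching (Bayesian-bootstrap-perturbed fit, donor pool of 5, random
tie-breaks, so imputed values are always observed values) or a normal
model; binary variables use the 2-category polytomous fit. Auxiliary
variables may enter imputation models without entering the EWAS.

## The synthetic cohort

Because the methods are evaluated by simulation, the generator is
first-class, tested code. It emulates the marginal structure of a
well-known whole-blood smoking-EWAS cohort:

* sex: Bernoulli, 70.5% male;
* age: normal, mean 55.4 years, rounded to whole years, truncated to
  [18, 100]. Only the mean (55.4) and median (56) of the target cohort are
  published, not the spread; the SD defaults to 8 years, chosen once so
  that the male-and-57+ group is roughly 30% of the cohort and the two
  missingness mechanisms below both remove roughly a fifth of the smoking
  values — the regime the strategies were designed for;
* smoking: (never, former, current) with probabilities (0.386, 0.567,
  0.047), or a multinomial-logit model on age and sex when dependence is
  wanted.

Methylation is generated site-wise: null sites are standard normal noise;
each of `n_true` associated sites adds `beta_former` and `beta_current`
times the corresponding smoking indicators, with magnitudes uniform on
0.15–0.60 SD (the span of the complete-data effect sizes the strategies
were originally benchmarked against) and a 50/50 sign mix. All sites are
then standardized. An optional equicorrelated block structure stands in
for the local correlation of real arrays; the default draws sites
independently, since no particular correlation structure is canonical.

Missingness mechanisms are ordered rule lists over fully observed
covariates — missing-at-random by construction:

* **MM1**: smoking missing with probability 0.75 for males aged 57 or
  over ("57 or over" read as inclusive, `age >= 57`);
* **MM2**: 0.5 for males 57+, 0.125 for everyone else;
* **MCAR** and custom rule sets for calibration tests.

Under the default cohort both mechanisms remove a comparable ~22–24% of
smoking values, and within any (sex, age-band) stratum the smoking
distribution of missing and observed individuals agrees in expectation —
both properties are tested.

What the generator does **not** emulate: bounded, bimodal beta-value
distributions (sites are Gaussian in SD units); cell-type composition and
batch effects; realistic genome-wide correlation. Passing tests therefore
demonstrate the statistical behaviour of the strategies under clean MAR
conditions, not robustness to the technical structure of real arrays.

## Truth and metrics

"Truth" for every replicate is the EWAS on the complete (no-missingness)
data of that replicate — not the generating coefficients — so each
strategy is charged only for what missingness costs it. The true-positive
percentage is the share of complete-data-significant sites a strategy
recovers; the false-positive percentage is the share of the strategy's
significant sites that are not in the truth set (a false-discovery
proportion), reported `NaN` and excluded from averages when a strategy
finds nothing (the count of such repeats is reported). Bias tables follow
the three-group split: sites in the imputation model's selection, true
sites not selected, and all other sites, each divided by the sign of the
truth coefficient; the attenuation phenomenon appears as sign-consistent
negative bias (towards the null) in the "true, not selected" group of the
naive and Wu strategies.

## Reproducibility and numerical choices

All randomness flows from one base seed through named streams
(`stream_seed(seed, "bin", b, "imp", i)` and so on), so the cohort, the
methylation draw, each mechanism, each bin and each imputation are
independently reproducible, results are independent of bin execution
order, and identical seed + configuration gives bit-identical tables.
Further fixed choices: standardization uses the sample SD (`n - 1`) and is
idempotent; a zero-variance site is an error naming the site; the C-C
ranking for Wu candidates is ascending `min(p_former, p_current)` with
ties broken by site ID; the last random bin may be smaller than the
nominal size, consistent with the ceiling bin counts; methylation files
admit no missing token (covariate missingness only), and covariate files
encode missing cells as the literal `NA`.

## Problem sizes in the tests and acceptance script

The published comparison ran 482,739 sites on an HPC system. The package's
own studies run at desk scale, chosen once: the efficiency/power study at
464 individuals, 2,000 sites (40 true), MM1, `m = 20`, 10 repeats; the
bias-structure study at 300 sites (30 true), `m = 10`, 30 replicates; the
MAR-validity study at 150 sites (10 true), `m = 10`, 30 replicates per
mechanism; `scripts/acceptance.R` runs the 2,000-site study at 5 repeats
with all strategies. At these scales the qualitative findings —
the mean-SE ordering complete-case > separate > bins(10:1) > bins(3:1),
the power gain of every MI strategy, the attenuation of unselected true
sites under the selection strategies and its absence under the partition
strategies — are all reproduced; the exact published magnitudes belong to
the original cohort and scale and are not targets here.

## Known limitations

The engine imputes covariates only (methylation is assumed complete, as
its missingness is typically minimal and technical). Ordinal models and
random-forest imputation are out of scope, as are gene- or
distance-based binning (rejected in the original comparison for
collinearity and uneven bin sizes), genomic-control correction, and
cell-composition adjustment. The IPW comparator implements one generic
variant (logistic completeness model, optional stabilization, symmetric
quantile trimming at 0.99) with heteroskedasticity-robust SEs; it is
unbiased when its missingness model is correctly specified but, as
expected, less efficient than MI.
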