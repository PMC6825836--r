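# binmi — binned multiple imputation for EWAS with missing covariates

`binmi` is for analysts running epigenome-wide association studies (EWAS)
— or any analysis with one regression per feature across a high-dimensional
outcome — when a covariate of the analysis model is partly missing.
Dropping the incomplete individuals (a complete-case analysis) costs power;
ordinary multiple imputation is unbiased only if the imputation model
contains the analysis outcome, and in an EWAS *every CpG site* is an
outcome, so a single imputation model would need hundreds of thousands of
predictors. `binmi` implements the practical middle ground: partition the
sites into random bins of fixed size, impute the covariate once per bin
from `covariate ~ bin sites + age + sex`, and pool each bin's imputed
analyses for exactly the sites in that bin.

## What it provides

* **Six strategies** behind one call, `run_strategy()`: `complete_case`,
  `separate` (one imputation per site), `random_bins` (`ceiling(N/b)` bins
  of size `b`), `naive` (one model with all Bonferroni-significant
  complete-case sites), `wu` (forward-stepwise BIC selection from the top
  100 complete-case hits), and `wu_bins` (random bins with the Wu
  selection added to every bin).
* **An imputation engine**: ridge-penalized polytomous regression for
  categorical covariates (Newton solver in C++, cross-checked against
  `nnet::multinom`), predictive mean matching and normal models for
  continuous ones, and full chained equations over several incomplete
  covariates with auxiliary variables.
* **EWAS and pooling**: per-site OLS `CpG ~ age + sex + smoking` in
  standardized units, Rubin's rules with Barnard–Rubin degrees of freedom
  (pooled estimate `q̄`, total variance `T = W + (1 + 1/m)B`), and
  Bonferroni significance on `min(p_former, p_current) < α/N`.
* **A synthetic-data generator** emulating a smoking-EWAS cohort (70.5%
  male, mean age 55.4; smoking 38.6/56.7/4.7% never/former/current) with
  planted effects of 0.15–0.60 SD and two missing-at-random mechanisms:
  MM1 (smoking missing with probability 0.75 for males 57+) and MM2 (0.5
  for males 57+, 0.125 otherwise), both removing ~22% of values.
* **An evaluation harness** (`run_simulation_study()`) measuring each
  strategy's true/false-positive percentages against the complete-data
  "truth", mean pooled SE, and per-group bias, plus an
  inverse-probability-weighting comparator (`run_ipw_ewas()`).

Results are tibbles; `tidy()`, `glance()`, `autoplot()` and
`plot_performance()` are provided. A thin CLI lives at
`inst/cli/binmi.R` (`simulate`, `run`, `evaluate` subcommands).

## Worked example

```r
library(binmi)
library(dplyr)

cohort <- simulate_cohort(464, seed = 2)                  # age, sex, smoking
sim    <- simulate_methylation(cohort, 2000, 40, seed = 2) # 40 true sites
truth  <- run_ewas(sim$methylation, cohort)                # no-missingness EWAS
length(significant_sites(truth))
#> [1] 16

miss <- apply_missingness(cohort, mm1(), seed = 2)         # MAR missingness
mean(is.na(miss$smoking))
#> [1] 0.196

cc <- run_strategy(sim$methylation, miss, "complete_case")
mi <- run_strategy(sim$methylation, miss, "random_bins", bin_size = 45,
                   m = 20, seed = 2)
glance(cc); glance(mi)
#>   strategy          m n_bins n_sites n_significant bonferroni mean_se_former
#> 1 complete_case     1     NA    2000            12   0.000025          0.111
#> 1 random_bins      20     45    2000            14   0.000025          0.108
```

The binned imputation recovers two extra genome-wide-significant sites and
lowers the mean pooled standard error from 0.111 to 0.108 — the
power/efficiency gain over the complete-case analysis. Individual hits:

```r
tidy(mi) |> filter(significant) |> arrange(p.value) |> head(4)
#>   site_id   significant term   estimate std.error    df       p.value
#> 1 cg0000633 TRUE        former   -0.624    0.100   340. 0.00000000151
#> 2 cg0000736 TRUE        former    0.555    0.0999  391. 0.0000000503
#> 3 cg0000662 TRUE        former   -0.533    0.103   302. 0.000000471
#> 4 cg0001591 TRUE        former   -0.519    0.103   337. 0.000000684
```

Estimates are in per-site SD units of methylation (the matrix is
standardized per site); `df` is the Barnard–Rubin adjusted degrees of
freedom after pooling `m = 20` imputations.

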