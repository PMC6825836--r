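test_that("MCAR completeness gives weights near the analytic 1/0.8", {
  cohort <- simulate_cohort(5000, seed = 50)
  miss <- apply_missingness(cohort, mcar(0.2), seed = 50)
  w <- estimate_weights(miss, stabilize = FALSE, trim_quantile = 1)
  ww <- w$weight[w$complete]
  expect_lt(max(abs(ww - 1.25)), 0.05)
})

test_that("MM1 complete cases in the 75%-missing group get weights near 4", {
  # the missingness model must reflect the mechanism: MM1 acts on the
  # male-and-57+ group, so that indicator is the (correct) predictor
  cohort <- simulate_cohort(5000, seed = 51)
  miss <- apply_missingness(cohort, mm1(), seed = 51)
  miss$male57 <- as.numeric(miss$sex == "male" & miss$age >= 57)
  w <- estimate_weights(miss, predictors = "male57",
                        stabilize = FALSE, trim_quantile = 1)
  grp <- cohort$sex == "male" & cohort$age >= 57 & w$complete
  expect_lt(abs(mean(w$weight[grp]) - 4), 0.3)
  others <- !(cohort$sex == "male" & cohort$age >= 57) & w$complete
  expect_lt(abs(mean(w$weight[others]) - 1), 0.1)
})

test_that("fully complete data yield unit stabilized weights", {
  cohort <- simulate_cohort(200, seed = 52)
  w <- estimate_weights(cohort)
  expect_true(all(w$weight == 1))
  expect_false(any(w$trimmed))
})

test_that("stabilized weights sum to about the complete-case count", {
  cohort <- simulate_cohort(3000, seed = 53)
  miss <- apply_missingness(cohort, mm2(), seed = 53)
  w <- estimate_weights(miss, stabilize = TRUE, trim_quantile = 1)
  n_complete <- sum(w$complete)
  expect_lt(abs(sum(w$weight) / n_complete - 1), 0.05)
})

test_that("equal weights reproduce unweighted complete-case estimates", {
  cohort <- simulate_cohort(300, seed = 54)
  sim <- simulate_methylation(cohort, 20, 2, seed = 54)
  miss <- apply_missingness(cohort, mcar(0.15), seed = 54)
  w <- estimate_weights(miss, predictors = character(0), stabilize = TRUE,
                        trim_quantile = 1)
  ipw <- run_ipw_ewas(sim$methylation, miss, w)
  cc <- run_strategy(sim$methylation, miss, "complete_case")
  expect_equal(ipw$beta_former, cc$beta_former, tolerance = 1e-10)
})

test_that("sandwich SEs match sandwich::vcovHC on a single site", {
  skip_if_not_installed("sandwich")
  cohort <- simulate_cohort(400, seed = 55)
  sim <- simulate_methylation(cohort, 5, 1, seed = 55)
  miss <- apply_missingness(cohort, mm1(), seed = 55)
  w <- estimate_weights(miss, stabilize = TRUE, trim_quantile = 1)
  ipw <- run_ipw_ewas(sim$methylation, miss, w)

  keep <- w$complete
  d <- data.frame(y = sim$methylation[1, keep],
                  age = cohort$age[keep],
                  male = as.numeric(cohort$sex[keep] == "male"),
                  former = as.numeric(cohort$smoking[keep] == "former"),
                  current = as.numeric(cohort$smoking[keep] == "current"),
                  wt = w$weight[keep])
  fit <- lm(y ~ age + male + former + current, data = d, weights = wt)
  se_ref <- sqrt(diag(sandwich::vcovHC(fit, type = "HC0")))
  expect_equal(ipw$beta_former[1], unname(coef(fit)["former"]),
               tolerance = 1e-10)
  expect_equal(ipw$se_former[1], unname(se_ref["former"]),
               tolerance = 1e-8)
})

test_that("IPW is unbiased for a planted effect under MM1", {
  # correctly specified missingness model (the MM1 group indicator)
  biases <- vapply(1:20, function(r) {
    cohort <- simulate_cohort(400, seed = 60 + r)
    sim <- simulate_methylation(cohort, 10, 1,
                                effect_range_former = c(0.6, 0.6),
                                seed = 60 + r)
    truth <- run_ewas(sim$methylation, cohort)
    miss <- apply_missingness(cohort, mm1(), seed = 60 + r)
    miss$male57 <- as.numeric(miss$sex == "male" & miss$age >= 57)
    w <- estimate_weights(miss, predictors = "male57")
    ipw <- run_ipw_ewas(sim$methylation, miss, w)
    ts <- sim$truth$site_id[sim$truth$is_true]
    i <- match(ts, ipw$site_id)
    ipw$beta_former[i] - truth$beta_former[i]
  }, numeric(1))
  mc_se <- sd(biases) / sqrt(length(biases))
  expect_lt(abs(mean(biases)), 2 * mc_se + 1e-8)
})

test_that("IPW and MI agree on signs of strongly planted effects", {
  hits <- 0L
  total <- 0L
  for (r in 1:10) {
    cohort <- simulate_cohort(300, seed = 80 + r)
    sim <- simulate_methylation(cohort, 20, 2,
                                effect_range_former = c(0.8, 1),
                                seed = 80 + r)
    miss <- apply_missingness(cohort, mm1(), seed = 80 + r)
    ipw <- run_ipw_ewas(sim$methylation, miss)
    mi <- run_strategy(sim$methylation, miss, "random_bins", bin_size = 10,
                       m = 4, seed = 80 + r)
    ts <- sim$truth$site_id[sim$truth$is_true]
    i <- match(ts, ipw$site_id)
    hits <- hits + sum(sign(ipw$beta_former[i]) ==
                         sign(mi$beta_former[i]))
    total <- total + length(i)
  }
  expect_gte(hits / total, 0.95)
})

test_that("IPW is less efficient than binned MI", {
  ratios <- vapply(1:3, function(r) {
    cohort <- simulate_cohort(464, seed = 70 + r)
    sim <- simulate_methylation(cohort, 200, 8, seed = 70 + r)
    miss <- apply_missingness(cohort, mm1(), seed = 70 + r)
    miss$male57 <- as.numeric(miss$sex == "male" & miss$age >= 57)
    w <- estimate_weights(miss, predictors = "male57")
    ipw <- run_ipw_ewas(sim$methylation, miss, w)
    mi <- run_strategy(sim$methylation, miss, "random_bins", bin_size = 45,
                       m = 10, seed = 70 + r)
    mean(ipw$se_former) / mean(mi$se_former)
  }, numeric(1))
  expect_gt(mean(ratios), 1)
})

test_that("perfect separation in the missingness model is refused", {
  cohort <- composed_cohort(200, 0.5)
  cohort$smoking[cohort$sex == "male"] <- NA # completeness == female
  expect_error(estimate_weights(cohort, predictors = c("age", "sex")),
               "separation")
})
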