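test_that("ridge multinomial fitter agrees with nnet::multinom", {
  skip_if_not_installed("nnet")
  set.seed(8)
  n <- 400
  x1 <- rnorm(n)
  x2 <- rnorm(n)
  eta_f <- 0.5 + 0.8 * x1
  eta_c <- -0.5 - 0.6 * x2
  denom <- 1 + exp(eta_f) + exp(eta_c)
  u <- runif(n)
  y <- ifelse(u < exp(eta_f) / denom, 2L,
              ifelse(u < (exp(eta_f) + exp(eta_c)) / denom, 3L, 1L))
  X <- cbind(1, x1, x2)
  fit <- binmi:::fit_multinom_ridge(X, y, 3, ridge = 0, tol = 1e-10,
                                    maxit = 200)
  ref <- nnet::multinom(factor(y) ~ x1 + x2, trace = FALSE,
                        maxit = 500, reltol = 1e-14)
  expect_equal(unname(fit$coef), unname(t(coef(ref))), tolerance = 1e-4)
  expect_equal(fit$loglik, -ref$value, tolerance = 1e-6)
})

test_that("degenerate single-category target imputes that category", {
  d <- tibble::tibble(
    sample_id = paste0("s", 1:10), age = rnorm(10, 50),
    sex = factor(rep(c("female", "male"), 5), levels = c("female", "male")),
    smoking = factor(c(rep("former", 7), NA, NA, NA),
                     levels = c("never", "former", "current")))
  imp <- impute_polytomous(d, "smoking", c("age", "sex"), m = 3, seed = 1)
  for (k in 1:3) {
    expect_true(all(complete_datasets(imp, k)$smoking == "former"))
  }
})

test_that("a strongly separated case is imputed to its own side", {
  set.seed(2)
  n <- 80
  x <- c(rnorm(n, -2), rnorm(n, 2))
  d <- tibble::tibble(
    sample_id = paste0("s", seq_len(2 * n + 1)),
    x = c(x, -5),
    y = factor(c(rep("A", n), rep("B", n), NA), levels = c("A", "B")))
  imp <- impute_polytomous(d, "y", "x", m = 100, seed = 4)
  draws <- imp$targets$y$draws
  expect_gte(mean(draws == "A"), 0.95)
})

test_that("imputation without missing values is the identity", {
  d <- tiny_cohort()
  imp <- impute_polytomous(d, "smoking", c("age", "sex"), m = 3, seed = 1)
  expect_identical(complete_datasets(imp, 2), d)
  imp2 <- impute_chained(
    d, list(smoking = imputation_spec("polytomous", c("age", "sex"))),
    m = 2, seed = 1)
  expect_identical(complete_datasets(imp2, 1), d)
})

test_that("observed cells are immutable across all completions", {
  cohort <- simulate_cohort(150, seed = 6)
  miss <- apply_missingness(cohort, mm2(), seed = 6)
  obs <- which(!is.na(miss$smoking))
  imp <- impute_polytomous(miss, "smoking", c("age", "sex"), m = 6,
                           seed = 6)
  for (d in complete_datasets(imp)) {
    expect_identical(d$smoking[obs], miss$smoking[obs])
    expect_false(anyNA(d$smoking))
    expect_identical(d$age, miss$age)
  }
})

test_that("proper MI yields positive between-imputation variance", {
  cohort <- simulate_cohort(200, seed = 12)
  miss <- apply_missingness(cohort, mm1(), seed = 12)
  sim <- simulate_methylation(cohort, 10, 2,
                              effect_range_former = c(0.5, 0.5), seed = 12)
  res <- run_strategy(sim$methylation, miss, "random_bins", bin_size = 5,
                      m = 8, seed = 12)
  # recompute B from the pooled output: total > within would need W; use
  # the fact that pooled df is finite and below the complete-data df
  expect_true(all(res$df_former < 195))
})

test_that("predictors >= complete cases is rejected with advice", {
  d <- tiny_cohort()
  d$smoking[1] <- NA
  extra <- matrix(rnorm(6 * 10), nrow = 6)
  expect_error(
    impute_polytomous(d, "smoking", c("age", "sex"), extra = extra, m = 2,
                      seed = 1),
    "smaller bins")
})

test_that("PMM imputes only observed values, from the nearest donors", {
  # y = 2x exactly; donors around the missing case at x = 3 are 5.9, 6.1
  d <- tibble::tibble(
    sample_id = paste0("s", 1:8),
    x = c(1, 2, 2.95, 3.05, 4, 5, 6, 3),
    y = c(2, 4, 5.9, 6.1, 8, 10, 12, NA))
  imp <- impute_pmm(d, "y", "x", m = 30, donors = 2, seed = 3)
  expect_true(all(imp$targets$y$draws %in% c(5.9, 6.1)))

  cohort <- simulate_cohort(100, seed = 14)
  cohort$bw <- rnorm(100, 3500, 400)
  cohort$bw[sample(100, 20)] <- NA
  imp2 <- impute_pmm(cohort, "bw", c("age", "sex"), m = 5, seed = 14)
  observed <- cohort$bw[!is.na(cohort$bw)]
  expect_true(all(imp2$targets$bw$draws %in% observed))
})

test_that("chained equations reduce to single-variable imputation in law", {
  cohort <- simulate_cohort(250, seed = 15)
  miss <- apply_missingness(cohort, mm1(), seed = 15)
  spec <- list(smoking = imputation_spec("polytomous", c("age", "sex")))
  single <- impute_polytomous(miss, "smoking", c("age", "sex"), m = 40,
                              seed = 16)
  chained <- impute_chained(miss, spec, m = 40, n_cycles = 3, seed = 17)
  tab_s <- table(factor(single$targets$smoking$draws,
                        levels = levels(cohort$smoking)))
  tab_c <- table(factor(chained$targets$smoking$draws,
                        levels = levels(cohort$smoking)))
  expect_gt(suppressWarnings(chisq.test(rbind(tab_s, tab_c)))$p.value,
            0.001)
})

test_that("chained equations recover a cross-variable association", {
  set.seed(18)
  n <- 400
  x <- rnorm(n)
  z <- 1.5 * x + rnorm(n, 0, 0.5)
  d <- tibble::tibble(sample_id = paste0("s", 1:n), x = x, z = z)
  d$x[sample(n, 40)] <- NA
  d$z[sample(n, 40)] <- NA
  specs <- list(x = imputation_spec("pmm", "z"),
                z = imputation_spec("normal", "x"))
  imp <- impute_chained(d, specs, m = 10, n_cycles = 5, seed = 19)
  slopes <- vapply(complete_datasets(imp), function(cd)
    unname(coef(lm(z ~ x, data = cd))[2]), numeric(1))
  # generating slope 1.5; MC SE of the pooled slope is well under 0.1
  expect_lt(abs(mean(slopes) - 1.5), 0.15)
})

test_that("chained equations demand a spec for every incomplete variable", {
  d <- tiny_cohort()
  d$smoking[1] <- NA
  d$age[2] <- NA
  expect_error(
    impute_chained(d, list(smoking = imputation_spec("polytomous", "sex")),
                   m = 2, seed = 1),
    "age")
})
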