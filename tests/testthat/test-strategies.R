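test_that("bin counts follow the ceiling formula at array scale", {
  ids <- as.character(seq_len(482739))
  expect_identical(n_bins(make_random_bins(ids, 150, seed = 1)), 3219L)
  expect_identical(n_bins(make_random_bins(ids, 45, seed = 1)), 10728L)
  small <- make_random_bins(paste0("cg", 1:10), 10, seed = 1)
  expect_identical(n_bins(small), 1L)
  expect_setequal(small$bins[[1]], paste0("cg", 1:10))
})

test_that("random bins partition the site set for arbitrary (N, b)", {
  set.seed(25)
  for (case in 1:20) {
    N <- sample(1:500, 1)
    b <- sample(1:60, 1)
    ids <- paste0("cg", seq_len(N))
    scheme <- make_random_bins(ids, b, seed = case)
    expect_identical(n_bins(scheme), as.integer(ceiling(N / b)))
    expect_true(all(lengths(scheme$bins) <= b))
    expect_setequal(unlist(scheme$bins), ids)
    expect_identical(anyDuplicated(unlist(scheme$bins)), 0L)
  }
})

test_that("wu bins include the selection everywhere and obey the count", {
  ids <- paste0("cg", 1:100)
  sel <- c("cg7", "cg42")
  scheme <- make_wu_bins(ids, sel, bin_size = 10, seed = 2)
  expect_identical(n_bins(scheme), 13L) # ceiling(98 / 8)
  for (bin in scheme$bins) {
    expect_true(all(sel %in% bin))
    expect_lte(length(bin), 10)
  }
  # every non-selected site appears exactly once
  rest <- setdiff(unlist(scheme$bins), sel)
  expect_setequal(rest, setdiff(ids, sel))

  # property over random (N, b, s)
  set.seed(26)
  for (case in 1:15) {
    N <- sample(20:300, 1)
    b <- sample(3:40, 1)
    s <- sample(0:(b - 1), 1)
    ids <- paste0("cg", seq_len(N))
    sel <- sample(ids, s)
    scheme <- make_wu_bins(ids, sel, b, seed = case)
    expect_identical(n_bins(scheme),
                     as.integer(ceiling((N - s) / (b - s))))
  }

  # reduction: no selection gives the random-bins structure
  expect_identical(make_wu_bins(ids, character(), 10, seed = 5)$bins,
                   make_random_bins(ids, 10, seed = 5)$bins)
  # a selection that fills the bin is refused
  expect_error(make_wu_bins(ids, ids[1:10], bin_size = 10, seed = 1),
               "increase bin_size")
  # all but one site selected: a single bin
  expect_identical(
    n_bins(make_wu_bins(paste0("cg", 1:5), paste0("cg", 1:4), 6, seed = 1)),
    1L)
})

test_that("naive selection is the Bonferroni set, ordered and nested", {
  cohort <- simulate_cohort(2000, seed = 27)
  sim <- simulate_methylation(cohort, 300, 1,
                              effect_range_former = c(2, 2),
                              effect_range_current = c(2, 2), seed = 27)
  res <- run_ewas(sim$methylation, cohort)
  sel05 <- select_sites_naive(res, alpha = 0.05, n_tests = 300)
  sel01 <- select_sites_naive(res, alpha = 0.01, n_tests = 300)
  expect_true(sim$truth$site_id[sim$truth$is_true] %in% sel05)
  expect_true(all(sel01 %in% sel05)) # nested thresholds
  # ascending p order
  pmin_ <- pmin(res$p_former, res$p_current)[match(sel05, res$site_id)]
  expect_false(is.unsorted(pmin_))
})

test_that("Wu forward-stepwise BIC selects signal and resists noise", {
  cohort <- simulate_cohort(400, seed = 28)
  sim <- simulate_methylation(cohort, 200, 1,
                              effect_range_former = c(2, 2),
                              effect_range_current = c(2, 2), seed = 28)
  res <- run_ewas(sim$methylation, cohort)
  sel <- select_sites_wu(res, sim$methylation, cohort, top_k = 20)
  expect_identical(sel[1], sim$truth$site_id[sim$truth$is_true])

  expect_identical(select_sites_wu(res, sim$methylation, cohort,
                                   top_k = 0), character(0))

  # pure-noise candidates: BIC's log-n penalty keeps selections tiny
  sizes <- vapply(1:10, function(r) {
    cohort <- simulate_cohort(400, seed = 40 + r)
    sim <- simulate_methylation(cohort, 60, 0, seed = 40 + r)
    res <- run_ewas(sim$methylation, cohort)
    length(select_sites_wu(res, sim$methylation, cohort, top_k = 30))
  }, numeric(1))
  expect_gte(mean(sizes <= 2), 0.9)
})

test_that("complete_case equals the EWAS on complete rows only", {
  cohort <- simulate_cohort(250, seed = 29)
  sim <- simulate_methylation(cohort, 40, 4, seed = 29)
  miss <- apply_missingness(cohort, mm1(), seed = 29)
  cc <- run_strategy(sim$methylation, miss, "complete_case")
  keep <- !is.na(miss$smoking)
  direct <- run_ewas(sim$methylation[, keep], miss[keep, ], n_tests = 40)
  expect_equal(cc$beta_former, direct$beta_former, tolerance = 1e-12)
  expect_equal(cc$se_current, direct$se_current, tolerance = 1e-12)
})

test_that("zero missingness makes every strategy the complete-data EWAS", {
  cohort <- simulate_cohort(150, seed = 30)
  sim <- simulate_methylation(cohort, 30, 3, seed = 30)
  truth <- run_ewas(sim$methylation, cohort)
  for (strat in c("random_bins", "separate", "naive")) {
    res <- run_strategy(sim$methylation, cohort, strat, bin_size = 10,
                        m = 4, seed = 30)
    expect_equal(res$beta_former, truth$beta_former, tolerance = 1e-12)
    expect_equal(res$se_former, truth$se_former, tolerance = 1e-12)
    expect_equal(res$df_former, truth$df_former) # B = 0 => df_com
  }
})

test_that("binned strategies cover every site exactly once", {
  cohort <- simulate_cohort(200, seed = 31)
  sim <- simulate_methylation(cohort, 53, 5, seed = 31)
  miss <- apply_missingness(cohort, mm2(), seed = 31)
  for (strat in c("random_bins", "wu_bins", "naive")) {
    res <- run_strategy(sim$methylation, miss, strat, bin_size = 10,
                        m = 3, seed = 31)
    expect_identical(res$site_id, rownames(sim$methylation))
  }
})

test_that("strategy runs are deterministic in seed and config", {
  cohort <- simulate_cohort(180, seed = 32)
  sim <- simulate_methylation(cohort, 30, 3, seed = 32)
  miss <- apply_missingness(cohort, mm1(), seed = 32)
  a <- run_strategy(sim$methylation, miss, "random_bins", bin_size = 8,
                    m = 5, seed = 99)
  b <- run_strategy(sim$methylation, miss, "random_bins", bin_size = 8,
                    m = 5, seed = 99)
  expect_identical(a, b)
  c_ <- run_strategy(sim$methylation, miss, "random_bins", bin_size = 8,
                     m = 5, seed = 100)
  expect_false(identical(a$beta_former, c_$beta_former))
})

test_that("the separate strategy refuses silly scale without force", {
  cohort <- simulate_cohort(50, seed = 33)
  sim <- simulate_methylation(cohort, 20, 0, seed = 33)
  miss <- apply_missingness(cohort, mm1(), seed = 33)
  expect_error(run_strategy(sim$methylation, miss, "separate", m = 2,
                            seed = 1, max_separate = 10),
               "force")
  res <- run_strategy(sim$methylation, miss, "separate", m = 2, seed = 1,
                      max_separate = 10, force = TRUE)
  expect_identical(nrow(res), 20L)
})

test_that("an empty naive selection still imputes from age and sex", {
  cohort <- simulate_cohort(150, seed = 34)
  sim <- simulate_methylation(cohort, 25, 0, seed = 34)
  miss <- apply_missingness(cohort, mm1(), seed = 34)
  res <- run_strategy(sim$methylation, miss, "naive", m = 3, seed = 34)
  expect_identical(length(attr(res, "selected")), 0L)
  expect_false(anyNA(res$beta_former))
})
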