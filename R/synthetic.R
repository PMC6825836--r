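#' Simulate a smoking-EWAS cohort
#'
#' Draws a cohort of individuals with age, sex and three-level smoking
#' status, fully observed.  Defaults emulate the cohort the simulation study
#' targets: 70.5% male, age normal with mean 55.4 years (SD 8, rounded to
#' whole years and truncated to 18–100, which places the median near 56),
#' and smoking probabilities (never, former, current) = (0.386, 0.567,
#' 0.047).  When `smoking_logit` is supplied, smoking is drawn from a
#' multinomial-logit model on age and sex instead of the marginal
#' probabilities.
#'
#' @param n Number of individuals.
#' @param male_fraction Probability of male sex.
#' @param age_mean,age_sd Age distribution (years) before rounding and
#'   truncation.
#' @param smoking_probs Length-3 probability vector over
#'   (never, former, current); must sum to 1.
#' @param smoking_logit Optional list with components `former` and `current`,
#'   each `c(intercept, age, male)` log-odds coefficients versus never.
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return Tibble with columns `sample_id`, `age`, `sex` (factor
#'   female/male), `smoking` (factor never/former/current).
#' @export
#' @examples
#' simulate_cohort(5, seed = 1)
simulate_cohort <- function(n, male_fraction = 0.705,
                            age_mean = 55.4, age_sd = 8,
                            smoking_probs = c(never = 0.386, former = 0.567,
                                              current = 0.047),
                            smoking_logit = NULL, seed = 1L) {
  stopifnot(n >= 1, male_fraction >= 0, male_fraction <= 1, age_sd > 0)
  if (length(smoking_probs) != 3L || any(smoking_probs < 0) ||
      abs(sum(smoking_probs) - 1) > 1e-9)
    stop("smoking_probs must be 3 non-negative values summing to 1",
         call. = FALSE)
  lev <- c("never", "former", "current")
  with_stream(stream_seed(seed, "cohort"), {
    sex <- factor(ifelse(runif(n) < male_fraction, "male", "female"),
                  levels = c("female", "male"))
    age <- pmin(pmax(round(rnorm(n, age_mean, age_sd)), 18), 100)
    if (is.null(smoking_logit)) {
      smoking <- lev[1L + findInterval(runif(n), cumsum(smoking_probs)[1:2])]
    } else {
      male <- sex_indicator(sex)
      eta_f <- smoking_logit$former[1] + smoking_logit$former[2] * age +
        smoking_logit$former[3] * male
      eta_c <- smoking_logit$current[1] + smoking_logit$current[2] * age +
        smoking_logit$current[3] * male
      denom <- 1 + exp(eta_f) + exp(eta_c)
      p_f <- exp(eta_f) / denom
      p_c <- exp(eta_c) / denom
      u <- runif(n)
      smoking <- ifelse(u < p_f, "former",
                        ifelse(u < p_f + p_c, "current", "never"))
    }
    tibble::tibble(
      sample_id = sprintf("id%05d", seq_len(n)),
      age = as.numeric(age), sex = sex,
      smoking = factor(smoking, levels = lev)
    )
  })
}

#' Simulate a standardized methylation matrix with planted smoking effects
#'
#' Null sites are independent standard normal noise.  Each of the `n_true`
#' smoking-associated sites adds `beta_former * 1[former] +
#' beta_current * 1[current]` to the noise, with effect magnitudes drawn
#' uniformly from the given ranges (SD units of the unstandardized site)
#' and signs positive with probability `sign_mix` (former and current
#' effects at a site share their sign).  All sites are then standardized
#' per site, so reported effects are in per-site SD units.
#'
#' @param cohort A cohort tibble from [simulate_cohort()].
#' @param n_sites Total number of CpG sites.
#' @param n_true Number of smoking-associated sites (`<= n_sites`).
#' @param effect_range_former,effect_range_current Length-2 magnitude
#'   ranges for the planted effects.
#' @param sign_mix Fraction of true sites with positive sign.
#' @param block_correlation Optional `list(size =, rho =)` giving an
#'   equicorrelated block structure for the noise (real arrays are locally
#'   correlated; the default draws sites independently).
#' @param seed Integer seed.
#' @return List with `methylation` (standardized matrix, sites x
#'   individuals, rownames `cg...`, colnames the cohort sample IDs) and
#'   `truth`, a tibble `site_id, is_true, beta_former, beta_current` of the
#'   generating values.
#' @export
simulate_methylation <- function(cohort, n_sites, n_true,
                                 effect_range_former = c(0.15, 0.60),
                                 effect_range_current = c(0.15, 0.60),
                                 sign_mix = 0.5, block_correlation = NULL,
                                 seed = 1L) {
  stopifnot(n_sites >= 1, n_true >= 0)
  if (n_true > n_sites) stop("n_true exceeds n_sites", call. = FALSE)
  n <- nrow(cohort)
  site_ids <- sprintf("cg%07d", seq_len(n_sites))
  with_stream(stream_seed(seed, "methylation"), {
    if (is.null(block_correlation)) {
      noise <- matrix(rnorm(n_sites * n), nrow = n_sites)
    } else {
      bs <- block_correlation$size
      rho <- block_correlation$rho
      stopifnot(bs >= 1, rho >= 0, rho < 1)
      blocks <- rep(seq_len(ceiling(n_sites / bs)), each = bs)[seq_len(n_sites)]
      shared <- matrix(rnorm(max(blocks) * n), nrow = max(blocks))
      noise <- sqrt(rho) * shared[blocks, , drop = FALSE] +
        sqrt(1 - rho) * matrix(rnorm(n_sites * n), nrow = n_sites)
    }
    true_idx <- if (n_true > 0) sort(sample.int(n_sites, n_true)) else integer()
    beta_f <- beta_c <- numeric(n_sites)
    if (n_true > 0) {
      sgn <- ifelse(runif(n_true) < sign_mix, 1, -1)
      beta_f[true_idx] <- sgn * runif(n_true, effect_range_former[1],
                                      effect_range_former[2])
      beta_c[true_idx] <- sgn * runif(n_true, effect_range_current[1],
                                      effect_range_current[2])
      former <- as.numeric(cohort$smoking == "former")
      current <- as.numeric(cohort$smoking == "current")
      noise[true_idx, ] <- noise[true_idx, , drop = FALSE] +
        outer(beta_f[true_idx], former) + outer(beta_c[true_idx], current)
    }
    rownames(noise) <- site_ids
    colnames(noise) <- cohort$sample_id
    list(
      methylation = standardize_methylation(noise),
      truth = tibble::tibble(
        site_id = site_ids,
        is_true = seq_len(n_sites) %in% true_idx,
        beta_former = beta_f, beta_current = beta_c
      )
    )
  })
}

#' Missing-at-random mechanisms
#'
#' A mechanism is an ordered list of rules; each individual receives the
#' missingness probability of the *first* rule whose condition they match
#' (0 if none).  Conditions may reference only fully observed covariates,
#' which makes the mechanisms missing-at-random by construction.  The two
#' named mechanisms of the simulation study are provided: `mm1()` makes the
#' target missing with probability 0.75 for males aged 57 or over (nobody
#' else), and `mm2()` with probability 0.5 for males aged 57 or over and
#' 0.125 for everyone else.  `mcar(p)` is uniform missingness.
#'
#' @param condition Unquoted logical expression over cohort columns.
#' @param prob Missingness probability in `[0, 1]`.
#' @export
missing_rule <- function(condition, prob) {
  stopifnot(prob >= 0, prob <= 1)
  structure(list(condition = rlang::enquo(condition), prob = prob),
            class = "missing_rule")
}

#' @rdname missing_rule
#' @param name Mechanism label.
#' @param ... `missing_rule()`s, tried in order.
#' @export
mm_mechanism <- function(name, ...) {
  rules <- list(...)
  stopifnot(length(rules) >= 1L,
            all(vapply(rules, inherits, logical(1), "missing_rule")))
  structure(list(name = name, rules = rules), class = "mm_mechanism")
}

#' @rdname missing_rule
#' @export
mm1 <- function() {
  mm_mechanism("MM1", missing_rule(sex == "male" & age >= 57, 0.75))
}

#' @rdname missing_rule
#' @export
mm2 <- function() {
  mm_mechanism("MM2",
               missing_rule(sex == "male" & age >= 57, 0.5),
               missing_rule(TRUE, 0.125))
}

#' @rdname missing_rule
#' @param prob Missingness probability in `[0, 1]`.
#' @export
mcar <- function(prob) {
  mm_mechanism("MCAR", missing_rule(TRUE, prob))
}

#' Induce covariate missingness under a mechanism
#'
#' @param cohort Fully observed covariate tibble.
#' @param mechanism An [mm_mechanism()].
#' @param targets Character vector of columns to make missing (default
#'   `"smoking"`).
#' @param seed Integer seed.
#' @return The cohort with `NA` in the target columns where missingness was
#'   drawn; all other cells untouched.
#' @export
apply_missingness <- function(cohort, mechanism, targets = "smoking",
                              seed = 1L) {
  stopifnot(inherits(mechanism, "mm_mechanism"),
            all(targets %in% names(cohort)))
  n <- nrow(cohort)
  prob <- rep(0, n)
  assigned <- rep(FALSE, n)
  for (rule in mechanism$rules) {
    match <- rlang::eval_tidy(rule$condition, data = cohort)
    if (length(match) == 1L) match <- rep(match, n)
    if (anyNA(match))
      stop("missingness rule references a variable with missing values",
           call. = FALSE)
    take <- match & !assigned
    prob[take] <- rule$prob
    assigned <- assigned | match
  }
  with_stream(stream_seed(seed, "missingness", mechanism$name), {
    miss <- runif(n) < prob
    for (v in targets) cohort[[v]][miss] <- NA
  })
  cohort
}
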