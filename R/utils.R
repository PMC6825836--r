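#' Derive a deterministic sub-stream seed
#'
#' All randomness in the package flows from one base seed through named
#' streams, so that e.g. the cohort, the methylation draw, each missingness
#' mechanism, each bin and each imputation are independently reproducible
#' and independent of execution order.  The hash is a simple 31-multiplier
#' rolling hash over the string tokens, reduced modulo 2^31 - 1.
#'
#' @param seed Integer base seed.
#' @param ... Labels (coerced to character) naming the stream, e.g.
#'   `stream_seed(1, "bin", 12, "imp", 3)`.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' stream_seed(1, "cohort")
#' stream_seed(1, "bin", 2, "imp", 5)
stream_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- as.double(seed) %% 2147483647
  for (tok in list(...)) {
    for (cc in utf8ToInt(paste0("|", as.character(tok)))) {
      h <- (h * 31 + cc) %% 2147483647
    }
  }
  as.integer(h)
}

# run `code` under a local RNG state seeded with `seed`; the caller's RNG
# stream is untouched
with_stream <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# sex as a 0/1 male indicator (female reference)
sex_indicator <- function(sex) {
  if (is.factor(sex)) sex <- as.character(sex)
  if (is.numeric(sex)) return(as.numeric(sex != 0))
  as.numeric(sex == "male")
}
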