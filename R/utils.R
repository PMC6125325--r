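#' @importFrom stats pt rbinom rmultinom rlnorm rnorm runif var setNames
#' @importFrom utils head packageVersion read.delim write.table
NULL

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Derive independent sub-seeds from a master seed
#'
#' All randomness in the package flows from one master seed. Sub-stages
#' (baseline abundances, per-trial sampling, per-repetition shadow
#' permutations and forest fits, ...) each receive their own seed drawn here,
#' so any sub-simulation can be reproduced in isolation.
#'
#' @param seed Integer master seed.
#' @param n Number of sub-seeds to derive.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 1]`.
#' @export
#' @examples
#' deriveSeeds(42L, 3)
deriveSeeds <- function(seed, n) {
  stopifnot(length(seed) == 1L, is.finite(seed), n >= 0)
  withSeed(seed, sample.int(2147483646L, n, replace = FALSE))
}

# Consistent error helper: messages name the offending field/argument.
badInput <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

assertCountMatrix <- function(m, what = "counts") {
  if (!is.matrix(m) || !is.numeric(m))
    badInput("%s must be a numeric matrix", what)
  if (anyNA(m) || any(m < 0))
    badInput("%s must be nonnegative and NA-free", what)
  if (any(m != round(m)))
    badInput("%s must be integer-valued", what)
  invisible(m)
}
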