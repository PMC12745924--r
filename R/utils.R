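# Internal numerical helpers shared across modules.

logit <- function(p) log(p / (1 - p))

inv_logit <- function(x) 1 / (1 + exp(-x))

#' Derive a reproducible stage-specific seed from a root seed
#'
#' All randomness in the package flows from one root seed; each pipeline stage
#' draws from its own named substream so that changing one stage's sample sizes
#' never perturbs another stage's draws.
#'
#' @param seed Integer root seed.
#' @param stage Character stage label.
#' @return An integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483647)
}

# z-score a matrix/data.frame of covariates; returns scaled values plus the
# centring/scaling used, so fitted models can be applied to new data.
zscore_covariates <- function(x) {
  x <- as.data.frame(x)
  centers <- vapply(x, mean, numeric(1))
  scales <- vapply(x, stats::sd, numeric(1))
  scales[!is.finite(scales) | scales == 0] <- 1
  z <- as.data.frame(mapply(function(col, m, s) (col - m) / s, x, centers, scales,
                            SIMPLIFY = FALSE))
  list(z = z, center = centers, scale = scales)
}

# Apply a stored standardization to new covariate values.
apply_zscore <- function(x, center, scale) {
  x <- as.data.frame(x)
  nm <- names(center)
  as.data.frame(mapply(function(v, m, s) (v - m) / s, x[nm], center[nm], scale[nm],
                       SIMPLIFY = FALSE))
}

# Geometric mean of a strictly positive series.
geometric_mean <- function(x) {
  stopifnot(all(x > 0))
  exp(mean(log(x)))
}

# Potential scale reduction factor (split-chain R-hat) for a list of chains
# (numeric vectors of equal length).
split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(ch) {
    n <- length(ch) %/% 2
    list(ch[seq_len(n)], ch[n + seq_len(n)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  b <- n * stats::var(means)
  w <- mean(vars)
  if (w == 0) return(1)
  sqrt(((n - 1) / n * w + b / n) / w)
}
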