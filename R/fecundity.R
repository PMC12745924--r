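#' Fit a Bayesian litter-size regression on female SVL
#'
#' Relates embryo counts of gravid females to their SVL with a log-link count
#' regression, fitted by random-walk Metropolis. Supported families:
#' `"poisson"` (zero-truncated, the default: every gravid female carries at
#' least one embryo) and `"negbinomial"` (zero-truncated, with an
#' overdispersion parameter). SVL is centred internally. The pointwise
#' log-likelihood matrix is retained for leave-one-out comparison.
#'
#' Priors: `Normal(0, 5)` on the intercept and `Normal(0, 1)` on the SVL
#' slope (both on the log scale); `half-Normal(0, 5)` on the negative
#' binomial shape.
#'
#' @param gravid Data frame with columns `svl_mm` and `embryos` (n >= 10).
#' @param family `"poisson"` or `"negbinomial"`.
#' @param mcmc MCMC settings: `n_steps`, `burn_in`, `thin`, `n_chains`
#'   (defaults mirror a 4-chain, 4000-iteration, 2000-warmup design).
#' @param cap_litter If `TRUE` (default) the reported mean litter size is
#'   capped at the biological maximum of 8.
#' @param seed Integer seed.
#' @return A `fecundity_fit`: posterior matrix (`alpha`, `beta_svl`, and
#'   `shape` for the negative binomial), posterior means, `mean_litter`
#'   (posterior-mean expected litter size averaged over the observed SVLs),
#'   pointwise log-likelihood matrix `ll_points` (draws x observations),
#'   split R-hat values, and the data.
#' @export
fit_litter_model <- function(gravid,
                             family = c("poisson", "negbinomial"),
                             mcmc = list(n_steps = 4000L, burn_in = 2000L,
                                         thin = 2L, n_chains = 4L),
                             cap_litter = TRUE, seed = 1L) {
  family <- match.arg(family)
  stopifnot(nrow(gravid) >= 10, all(gravid$embryos >= 1))
  y <- gravid$embryos
  x <- gravid$svl_mm - mean(gravid$svl_mm)
  n_par <- if (family == "poisson") 2L else 3L

  point_ll <- function(th) {
    mu <- exp(th[1] + th[2] * x)
    if (family == "poisson") {
      stats::dpois(y, mu, log = TRUE) - stats::ppois(0, mu, lower.tail = FALSE,
                                                     log.p = TRUE)
    } else {
      size <- th[3]
      stats::dnbinom(y, mu = mu, size = size, log = TRUE) -
        stats::pnbinom(0, mu = mu, size = size, lower.tail = FALSE, log.p = TRUE)
    }
  }
  log_post <- function(th) {
    if (n_par == 3L && th[3] <= 0) return(-Inf)
    ll <- sum(point_ll(th))
    if (!is.finite(ll)) return(-Inf)
    ll + stats::dnorm(th[1], 0, 5, log = TRUE) +
      stats::dnorm(th[2], 0, 1, log = TRUE) +
      (if (n_par == 3L) stats::dnorm(th[3], 0, 5, log = TRUE) else 0)
  }

  set.seed(stage_seed(seed, paste0("fecundity_", family)))
  chains <- vector("list", mcmc$n_chains)
  for (ch in seq_len(mcmc$n_chains)) {
    th <- c(log(mean(y)) + stats::rnorm(1, 0, 0.3), stats::rnorm(1, 0, 0.05),
            if (n_par == 3L) stats::runif(1, 1, 20))
    lp <- log_post(th)
    sd_prop <- c(0.1, 0.02, if (n_par == 3L) 2)
    keep <- matrix(NA_real_, 0, n_par)
    n_acc <- 0
    for (s in seq_len(mcmc$n_steps)) {
      cand <- th + stats::rnorm(n_par, 0, sd_prop)
      lp_cand <- log_post(cand)
      if (log(stats::runif(1)) < lp_cand - lp) {
        th <- cand; lp <- lp_cand; n_acc <- n_acc + 1
      }
      if (s <= mcmc$burn_in && s %% 100 == 0) {
        sd_prop <- sd_prop * exp(n_acc / s - 0.3)
      }
      if (s > mcmc$burn_in && (s - mcmc$burn_in) %% mcmc$thin == 0) {
        keep <- rbind(keep, th)
      }
    }
    chains[[ch]] <- keep
  }
  post <- do.call(rbind, chains)
  colnames(post) <- c("alpha", "beta_svl", if (n_par == 3L) "shape")
  rhat <- vapply(seq_len(n_par),
                 function(j) split_rhat(lapply(chains, function(c) c[, j])),
                 numeric(1))
  names(rhat) <- colnames(post)

  ll_points <- t(apply(post, 1, point_ll))
  # expected litter per draw: truncated-family mean averaged over observed SVL
  mean_draws <- apply(post, 1, function(th) {
    mu <- exp(th[1] + th[2] * x)
    if (family == "poisson") mean(mu / (1 - exp(-mu)))
    else {
      p0 <- stats::dnbinom(0, mu = mu, size = th[3])
      mean(mu / (1 - p0))
    }
  })
  mean_litter <- mean(mean_draws)
  if (cap_litter) mean_litter <- min(mean_litter, 8)

  out <- list(family = family, posterior = post,
              alpha = mean(post[, "alpha"]), beta_svl = mean(post[, "beta_svl"]),
              mean_litter = mean_litter, ll_points = ll_points,
              rhat = rhat, data = gravid)
  class(out) <- "fecundity_fit"
  out
}

#' @export
print.fecundity_fit <- function(x, ...) {
  ci <- stats::quantile(x$posterior[, "beta_svl"], c(0.025, 0.975))
  cat(sprintf(
    "Litter-size fit (%s, n = %d): alpha = %.3f, beta_svl = %.4f [%.4f, %.4f],\n  mean litter = %.2f, max split R-hat = %.3f\n",
    x$family, nrow(x$data), x$alpha, x$beta_svl, ci[1], ci[2], x$mean_litter,
    max(x$rhat)))
  invisible(x)
}

# Pareto-smoothed importance sampling weights for one observation's
# leave-one-out ratios (log scale in, normalised weights out). The largest
# 20% of raw ratios are replaced by quantiles of a generalised Pareto
# distribution fitted to them (method-of-moments style estimator).
psis_weights <- function(log_ratios) {
  lr <- log_ratios - max(log_ratios)
  w <- exp(lr)
  s <- length(w)
  m <- max(ceiling(0.2 * s), 5)
  ord <- order(w)
  tail_idx <- ord[(s - m + 1):s]
  tail_w <- w[tail_idx]
  u <- min(tail_w)
  exc <- tail_w - u
  if (stats::sd(exc) > 0) {
    # generalised Pareto fit by probability-weighted moments
    mean_e <- mean(exc)
    var_e <- stats::var(exc)
    xi <- 0.5 * (1 - mean_e^2 / var_e)
    sigma <- 0.5 * mean_e * (mean_e^2 / var_e + 1)
    if (is.finite(xi) && is.finite(sigma) && sigma > 0) {
      q <- (seq_len(m) - 0.5) / m
      smoothed <- if (abs(xi) < 1e-8) u - sigma * log1p(-q)
                  else u + sigma / xi * ((1 - q)^(-xi) - 1)
      w[tail_idx] <- pmin(sort(smoothed), max(w))
    }
    k_hat <- xi
  } else {
    k_hat <- 0
  }
  list(w = w / sum(w), k_hat = k_hat)
}

# expected log pointwise predictive density via PSIS-LOO for one fit
psis_loo <- function(ll_points) {
  n <- ncol(ll_points)
  elpd_i <- numeric(n)
  k_hat <- numeric(n)
  for (i in seq_len(n)) {
    pw <- psis_weights(-ll_points[, i])
    elpd_i[i] <- log(sum(pw$w * exp(ll_points[, i] - max(ll_points[, i])))) +
      max(ll_points[, i])
    k_hat[i] <- pw$k_hat
  }
  list(elpd = sum(elpd_i), elpd_i = elpd_i, k_hat = k_hat)
}

#' Compare litter-size models by leave-one-out cross-validation
#'
#' Ranks fitted models by the PSIS-LOO expected log predictive density
#' computed from their stored pointwise log-likelihoods.
#'
#' @param fits Named list of `fecundity_fit` objects sharing the same data.
#' @return A data frame ranked by `elpd_loo` (higher is better) with the
#'   difference to the best model and its standard error.
#' @export
compare_loo <- function(fits) {
  stopifnot(length(fits) >= 1)
  datas <- lapply(fits, function(f) f$data)
  if (!all(vapply(datas, identical, logical(1), y = datas[[1]]))) {
    stop("fits must share the same data for LOO comparison")
  }
  loos <- lapply(fits, function(f) psis_loo(f$ll_points))
  elpd <- vapply(loos, function(l) l$elpd, numeric(1))
  nm <- if (is.null(names(fits))) vapply(fits, function(f) f$family, character(1))
        else names(fits)
  ord <- order(elpd, decreasing = TRUE)
  best_i <- ord[1]
  se_diff <- vapply(seq_along(fits), function(i) {
    d <- loos[[i]]$elpd_i - loos[[best_i]]$elpd_i
    sqrt(length(d) * stats::var(d))
  }, numeric(1))
  out <- data.frame(model = nm[ord], elpd_loo = elpd[ord],
                    elpd_diff = elpd[ord] - elpd[best_i],
                    se_diff = se_diff[ord],
                    max_k_hat = vapply(loos, function(l) max(l$k_hat),
                                       numeric(1))[ord])
  rownames(out) <- NULL
  out
}
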