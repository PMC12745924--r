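#' Enumerate the additive Cormack-Jolly-Seber candidate model set
#'
#' Crosses every additive subset of the three monthly covariates (maximum
#' temperature, precipitation, mean SVL) on survival with every subset on
#' detection: 8 x 8 = 64 candidate models, each with intercepts always
#' present, in a deterministic order (survival terms vary slowest).
#'
#' @return A list of 64 model specifications, each a list with character
#'   vectors `phi_terms` and `p_terms`.
#' @export
enumerate_models <- function() {
  covs <- c("tmax", "precip", "mean_svl")
  subsets <- lapply(0:7, function(m) covs[bitwAnd(m, c(1L, 2L, 4L)) > 0])
  out <- list()
  for (ph in subsets) for (pp in subsets) {
    out[[length(out) + 1L]] <- list(phi_terms = ph, p_terms = pp)
  }
  out
}

# design matrix (intercept + named covariate columns) for a term subset
cjs_design <- function(covariates, terms) {
  x <- matrix(1, nrow(covariates), 1)
  if (length(terms)) x <- cbind(x, as.matrix(covariates[terms]))
  x
}

#' Cormack-Jolly-Seber log-likelihood with time-varying covariates
#'
#' Computes the CJS likelihood conditioned on first capture. Monthly survival
#' `phi_t` (occasion `t` to `t+1`) and detection `p_t` (at occasion `t`) are
#' logit-linear in the covariates of occasion `t`. Terminal non-detection is
#' handled by the standard chi recursion
#' `chi_t = (1 - phi_t) + phi_t * (1 - p_{t+1}) * chi_{t+1}`, evaluated
#' simultaneously for all individuals by vectorised backward/forward passes.
#'
#' @param histories 0/1 matrix, one row per individual, one column per
#'   monthly occasion; every row must contain at least one capture.
#' @param covariates Data frame with one row per occasion holding the
#'   (already standardised) columns named by `spec`.
#' @param spec A model specification from [enumerate_models()].
#' @param beta Numeric vector: survival coefficients (intercept then
#'   `phi_terms`) followed by detection coefficients (intercept then
#'   `p_terms`).
#' @return The total log-likelihood.
#' @export
cjs_loglik <- function(histories, covariates, spec, beta) {
  if (any(rowSums(histories) == 0)) stop("history with no capture")
  T <- ncol(histories)
  xphi <- cjs_design(covariates, spec$phi_terms)
  xp <- cjs_design(covariates, spec$p_terms)
  n_phi <- ncol(xphi)
  stopifnot(length(beta) == n_phi + ncol(xp))
  phi <- inv_logit(drop(xphi %*% beta[seq_len(n_phi)]))[seq_len(T - 1)]
  p <- inv_logit(drop(xp %*% beta[-seq_len(n_phi)]))  # p_t at occasion t

  first <- apply(histories, 1, function(h) which(h == 1)[1])
  last <- apply(histories, 1, function(h) max(which(h == 1)))

  # chi_t: probability of never being seen after occasion t
  chi <- rep(1, T)
  for (t in (T - 1):1) {
    chi[t] <- (1 - phi[t]) + phi[t] * (1 - p[t + 1]) * chi[t + 1]
  }

  # between first and last capture the animal is known alive:
  # each interval contributes log(phi_t), each occasion log(p) or log(1-p)
  lphi <- c(log(phi), 0)
  lp <- log(p); lq <- log1p(-p)
  cum_phi <- cumsum(c(0, lphi))        # cum_phi[t+1] = sum_{s<t+1} log phi_s
  ll <- 0
  n <- nrow(histories)
  for (i in seq_len(n)) {
    f <- first[i]; l <- last[i]
    li <- log(chi[l])
    if (l > f) {
      mid <- (f + 1):l
      li <- li + cum_phi[l] - cum_phi[f] +
        sum(ifelse(histories[i, mid] == 1, lp[mid], lq[mid]))
    }
    ll <- ll + li
  }
  ll
}

# fast path used by the optimiser: identical model, grouped by unique
# (first, last, detection-pattern) sufficient statistics
cjs_loglik_grouped <- function(groups, covariates, spec, beta) {
  T <- groups$T
  xphi <- cjs_design(covariates, spec$phi_terms)
  xp <- cjs_design(covariates, spec$p_terms)
  n_phi <- ncol(xphi)
  phi <- inv_logit(drop(xphi %*% beta[seq_len(n_phi)]))[seq_len(T - 1)]
  p <- inv_logit(drop(xp %*% beta[-seq_len(n_phi)]))
  chi <- rep(1, T)
  for (t in (T - 1):1) {
    chi[t] <- (1 - phi[t]) + phi[t] * (1 - p[t + 1]) * chi[t + 1]
  }
  lphi <- log(phi)
  cum_phi <- cumsum(c(0, lphi))
  lp <- log(p); lq <- log1p(-p)
  sum(groups$w_chi * log(chi)) +
    sum(groups$w_interval * c(lphi, 0)) +
    sum(groups$w_det * lp) + sum(groups$w_miss * lq)
}

# sufficient statistics for the grouped likelihood
cjs_groups <- function(histories) {
  if (any(rowSums(histories) == 0)) stop("history with no capture")
  T <- ncol(histories)
  first <- apply(histories, 1, function(h) which(h == 1)[1])
  last <- apply(histories, 1, function(h) max(which(h == 1)))
  w_chi <- tabulate(last, T)
  # count of intervals t->t+1 inside (first, last] across individuals
  w_interval <- rep(0, T - 1)
  w_det <- rep(0, T); w_miss <- rep(0, T)
  for (i in seq_len(nrow(histories))) {
    f <- first[i]; l <- last[i]
    if (l > f) {
      w_interval[f:(l - 1)] <- w_interval[f:(l - 1)] + 1
      mid <- (f + 1):l
      det <- histories[i, mid] == 1
      w_det[mid[det]] <- w_det[mid[det]] + 1
      w_miss[mid[!det]] <- w_miss[mid[!det]] + 1
    }
  }
  list(T = T, w_chi = w_chi, w_interval = c(w_interval, 0),
       w_det = w_det, w_miss = w_miss)
}

#' Fit one CJS model by maximum likelihood
#'
#' @param histories 0/1 capture-history matrix.
#' @param covariates Standardised covariate data frame (one row per occasion).
#' @param spec Model specification.
#' @param n_starts Number of optimiser starts (the first from zero, the rest
#'   jittered).
#' @return A `cjs_fit` list: `spec`, `beta_phi`, `beta_p`, `loglik`,
#'   `n_params`, `aic`, `converged`, plus the standardisation recipe.
#' @export
fit_cjs <- function(histories, covariates, spec, n_starts = 1L) {
  groups <- cjs_groups(histories)
  n_par <- 2L + length(spec$phi_terms) + length(spec$p_terms)
  nll <- function(b) -cjs_loglik_grouped(groups, covariates, spec, b)
  best <- NULL
  for (s in seq_len(n_starts)) {
    init <- if (s == 1) rep(0, n_par) else stats::rnorm(n_par, 0, 0.5)
    opt <- tryCatch(
      stats::optim(init, nll, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best)) stop("CJS optimisation failed for model")
  n_phi <- 1L + length(spec$phi_terms)
  ll <- -best$value
  out <- list(spec = spec,
              beta_phi = stats::setNames(best$par[seq_len(n_phi)],
                                         c("intercept", spec$phi_terms)),
              beta_p = stats::setNames(best$par[-seq_len(n_phi)],
                                       c("intercept", spec$p_terms)),
              loglik = ll, n_params = n_par,
              aic = -2 * ll + 2 * n_par,
              converged = best$convergence == 0)
  class(out) <- "cjs_fit"
  out
}

#' Fit all 64 candidate CJS models and select by AIC
#'
#' Maximises every candidate model, assembles an AIC table with delta-AIC and
#' Akaike weights, and returns the best model. Ties in AIC are broken toward
#' fewer parameters. Covariates are z-scored internally; the scaling is
#' stored on the returned fit so it can be applied to new environments.
#'
#' @param histories 0/1 capture-history matrix (>= 3 occasions).
#' @param covariates Raw covariate data frame with columns `tmax`, `precip`,
#'   `mean_svl` (one row per occasion).
#' @param n_starts Optimiser starts per model.
#' @return A list with `table` (data frame: model label, phi/p terms,
#'   n_params, loglik, aic, delta_aic, weight, converged, sorted by AIC) and
#'   `best` (the winning `cjs_fit`, carrying `center`/`scale`).
#' @export
fit_all_and_select <- function(histories, covariates, n_starts = 1L) {
  stopifnot(ncol(histories) >= 3)
  zc <- zscore_covariates(covariates[, c("tmax", "precip", "mean_svl")])
  specs <- enumerate_models()
  fits <- vector("list", length(specs))
  rows <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    f <- tryCatch(fit_cjs(histories, zc$z, sp, n_starts = n_starts),
                  error = function(e) NULL)
    fits[[i]] <- f
    rows[[i]] <- data.frame(
      model = sprintf("phi(%s) p(%s)",
                      paste(c("1", sp$phi_terms), collapse = "+"),
                      paste(c("1", sp$p_terms), collapse = "+")),
      phi_terms = paste(sp$phi_terms, collapse = "+"),
      p_terms = paste(sp$p_terms, collapse = "+"),
      n_params = 2L + length(sp$phi_terms) + length(sp$p_terms),
      loglik = if (is.null(f)) NA_real_ else f$loglik,
      aic = if (is.null(f)) NA_real_ else f$aic,
      converged = if (is.null(f)) FALSE else f$converged)
  }
  tab <- do.call(rbind, rows)
  ord <- order(tab$aic, tab$n_params)  # AIC ties broken toward fewer parameters
  tab <- tab[ord, ]
  tab$delta_aic <- tab$aic - min(tab$aic, na.rm = TRUE)
  w <- exp(-0.5 * tab$delta_aic)
  tab$weight <- w / sum(w, na.rm = TRUE)
  rownames(tab) <- NULL
  best <- fits[[ord[1]]]
  best$center <- zc$center
  best$scale <- zc$scale
  list(table = tab, best = best)
}

#' Monthly survival series from a fitted CJS model
#'
#' Applies the fitted survival coefficients to each occasion's covariates.
#'
#' @param fit A `cjs_fit` from [fit_all_and_select()] (carrying the
#'   standardisation) or [fit_cjs()] (then `covariates` must already be
#'   standardised).
#' @param covariates Covariate data frame, one row per month.
#' @return Numeric vector of monthly survival probabilities.
#' @export
monthly_survival_series <- function(fit, covariates) {
  z <- if (!is.null(fit$center)) {
    apply_zscore(covariates, fit$center, fit$scale)
  } else {
    as.data.frame(covariates)
  }
  x <- cjs_design(z, fit$spec$phi_terms)
  inv_logit(drop(x %*% fit$beta_phi))
}
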