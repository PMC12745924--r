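#' Von Bertalanffy length after an elapsed interval (Fabens form)
#'
#' `L1 = L0 + (Linf - L0) * (1 - exp(-k * dt))`: the expected SVL after `dt`
#' months of growth from `L0`, without needing the age at first capture.
#'
#' @param L0 SVL at the earlier capture (mm); must be below `Linf`.
#' @param Linf Asymptotic SVL (mm).
#' @param k Monthly growth coefficient (1/month, > 0).
#' @param dt Elapsed time (months, >= 0).
#' @return Expected SVL (mm); strictly increasing in `dt`, bounded by `Linf`.
#' @export
predict_length <- function(L0, Linf, k, dt) {
  stopifnot(k > 0, all(dt >= 0), all(L0 >= 0))
  if (any(L0 >= Linf)) {
    stop("L0 >= Linf: SVL must never exceed the asymptotic size")
  }
  L0 + (Linf - L0) * (1 - exp(-k * dt))
}

#' Age from length by inverting the von Bertalanffy curve
#'
#' `a = t0 + (1/k) * log(Linf / (Linf - L))`, the growth curve solved for
#' age. `t0` is the theoretical age at SVL zero; anchoring `t0` so that the
#' curve passes through the neonate SVL at age 0 makes the returned ages
#' post-partum ages in months.
#'
#' @param L SVL (mm), below `Linf`.
#' @param Linf Asymptotic SVL (mm).
#' @param k Monthly growth coefficient (1/month).
#' @param t0 Theoretical age at SVL 0 (months).
#' @return Age in months.
#' @export
age_from_length <- function(L, Linf, k, t0 = 0) {
  stopifnot(all(L >= 0))
  if (any(L >= Linf)) stop("L >= Linf: age undefined at or beyond the asymptote")
  t0 + log(Linf / (Linf - L)) / k
}

# t0 that anchors the growth curve at `birth_svl` mm at age 0
t0_for_birth_svl <- function(Linf, k, birth_svl) {
  -log(Linf / (Linf - birth_svl)) / k
}

#' Fit the Fabens growth model with individual variation in k
#'
#' Fits `L1 = L0 + (Linf - L0) * (1 - exp(-k_i * dt)) + eps` to
#' consecutive-recapture intervals by a nonlinear mixed-effects model in
#' which the growth coefficient `k_i` varies among individuals
#' (`k_i ~ Normal(k_fixed, k_random_sd)`), via [nlme::nlme()]. Starting
#' values follow the standard recipe: initial `Linf` is the largest observed
#' SVL and initial `k` the mean of `dSVL/dt`. If the random effect cannot be
#' estimated (fewer than two individuals with multiple intervals, or a
#' degenerate fit), the model falls back to fixed-effects nonlinear least
#' squares with `k_random_sd = 0` and a warning.
#'
#' Intervals flagged as starting at or above the asymptote estimate
#' (`flag_linf`) are removed before fitting.
#'
#' @param intervals A `recapture_intervals` data frame (one sex).
#' @param sex Optional: restrict to `"F"` or `"M"` rows.
#' @param birth_svl Neonate SVL (mm) used to anchor `t0` so the predictive
#'   curve starts at the neonate size at age 0.
#' @param max_iter,pnls_max_iter,tol Optimiser control: maximum outer
#'   iterations, maximum penalised nonlinear least-squares iterations per
#'   step, and convergence tolerance.
#' @return An object of class `growth_fit`: list with `Linf`, `k_fixed`,
#'   `k_random_sd`, `t0`, `sigma_resid`, `conditional_r2`, `n_intervals`,
#'   `n_individuals`, `sex`, `birth_svl` and `method` ("nlme" or "nls").
#' @export
fit_fabens_mixed <- function(intervals, sex = NULL, birth_svl = 35,
                             max_iter = 5000L, pnls_max_iter = 1000L,
                             tol = 6e-6) {
  d <- as.data.frame(intervals)
  if (!is.null(sex)) d <- d[d$sex == sex, ]
  if (!is.null(d$flag_linf)) d <- d[!d$flag_linf, ]
  if (nrow(d) < 10) stop("need at least 10 recapture intervals")
  d$id <- factor(d$id)

  linf_init <- max(c(d$L0, d$L1))
  k_init <- mean((d$L1 - d$L0) / (d$dt * pmax(linf_init - d$L0, 1)))
  k_init <- max(k_init, 1e-3)

  multi <- sum(table(d$id) > 1) >= 2
  fit <- NULL
  method <- "nlme"
  if (multi) {
    fit <- tryCatch(
      nlme::nlme(
        L1 ~ L0 + (Linf - L0) * (1 - exp(-k * dt)),
        fixed = Linf + k ~ 1,
        random = k ~ 1 | id,
        data = d,
        start = c(Linf = linf_init, k = k_init),
        control = nlme::nlmeControl(maxIter = max_iter,
                                    pnlsMaxIter = pnls_max_iter,
                                    tolerance = tol, returnObject = FALSE)),
      error = function(e) NULL)
  }
  if (is.null(fit)) {
    method <- "nls"
    if (multi) warning("mixed-effects fit failed; falling back to fixed-effects Fabens")
    else warning("fewer than 2 individuals with multiple intervals; k_random_sd fixed at 0")
    fit <- tryCatch(
      stats::nls(L1 ~ L0 + (Linf - L0) * (1 - exp(-k * dt)), data = d,
                 start = c(Linf = linf_init, k = k_init),
                 control = stats::nls.control(maxiter = max_iter,
                                              tol = 1e-10, minFactor = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- stats::coef(fit)
      pred <- stats::fitted(fit)
      sigma_ls <- stats::sigma(fit)
    } else {
      # direct least squares: robust when residual variance is (near) zero
      method <- "ls"
      sse <- function(par) {
        mu <- d$L0 + (exp(par[1]) - d$L0) * (1 - exp(-exp(par[2]) * d$dt))
        sum((d$L1 - mu)^2)
      }
      opt <- stats::optim(c(log(linf_init), log(k_init)), sse,
                          control = list(maxit = max_iter, reltol = 1e-14))
      cf <- c(Linf = exp(opt$par[1]), k = exp(opt$par[2]))
      pred <- d$L0 + (cf["Linf"] - d$L0) * (1 - exp(-cf["k"] * d$dt))
      sigma_ls <- sqrt(opt$value / max(nrow(d) - 2, 1))
    }
    k_sd <- 0
  } else {
    cf <- nlme::fixef(fit)
    pred <- as.numeric(stats::fitted(fit, level = 1))  # conditional predictions
    k_sd <- suppressWarnings(as.numeric(nlme::VarCorr(fit)["k", "StdDev"]))
  }
  sigma <- if (method == "ls") sigma_ls else stats::sigma(fit)
  r2 <- if (stats::var(d$L1) == 0) 1 else
    stats::cor(pred, d$L1)^2
  out <- list(Linf = unname(cf["Linf"]), k_fixed = unname(cf["k"]),
              k_random_sd = k_sd,
              t0 = t0_for_birth_svl(unname(cf["Linf"]), unname(cf["k"]), birth_svl),
              sigma_resid = max(sigma, 1e-8),
              conditional_r2 = r2,
              n_intervals = nrow(d), n_individuals = nlevels(d$id),
              sex = if (is.null(sex)) "all" else sex,
              birth_svl = birth_svl, method = method)
  class(out) <- "growth_fit"
  out
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf(
    "Fabens growth fit (%s, sex %s): Linf = %.2f mm, k = %.4f /month (SD %.4f),\n  sigma = %.2f mm, conditional R2 = %.3f, %d intervals / %d individuals\n",
    x$method, x$sex, x$Linf, x$k_fixed, x$k_random_sd, x$sigma_resid,
    x$conditional_r2, x$n_intervals, x$n_individuals))
  invisible(x)
}

#' Monthly growth transition matrix on a size mesh
#'
#' `G[j, i]` is the probability that an individual at mesh size `x_i` is at
#' mesh size `y_j` one month later: a normal density centred on the von
#' Bertalanffy one-month prediction with SD `sigma_resid`, discretised by the
#' midpoint rule and renormalised so each column sums to one (eviction
#' correction: probability mass falling outside the mesh is returned to it,
#' so the survival-growth kernel loses mass only through survival).
#'
#' @param x_mesh Mesh midpoints (mm).
#' @param fit A `growth_fit`.
#' @return A `length(x_mesh)` square matrix with unit column sums.
#' @export
growth_transition <- function(x_mesh, fit) {
  # direct Fabens formula: sizes at/above Linf shrink back toward it, which
  # keeps the kernel defined on mesh points beyond the asymptote
  mu <- x_mesh + (fit$Linf - x_mesh) * (1 - exp(-fit$k_fixed))
  sd <- max(fit$sigma_resid, 1e-8)
  g <- outer(x_mesh, mu, function(y, m) stats::dnorm(y, m, sd))
  cs <- colSums(g)
  if (any(cs == 0)) { # degenerate SD: put all mass on the nearest mesh point
    for (i in which(cs == 0)) {
      g[which.min(abs(x_mesh - mu[i])), i] <- 1
    }
    cs <- colSums(g)
  }
  sweep(g, 2, cs, "/")
}

#' Predictive growth curve (expected SVL as a function of age)
#'
#' The population-level von Bertalanffy trajectory anchored at the neonate
#' SVL at age 0.
#'
#' @param fit A `growth_fit`.
#' @param ages Ages in months (>= 0).
#' @return A data frame with columns `age` and `svl`.
#' @export
predictive_growth_curve <- function(fit, ages) {
  stopifnot(all(ages >= 0))
  svl <- fit$birth_svl + (fit$Linf - fit$birth_svl) * (1 - exp(-fit$k_fixed * ages))
  data.frame(age = ages, svl = svl)
}
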