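#' Size mesh for the IPM
#'
#' Midpoint-rule discretisation of the SVL axis: `n` equally spaced mesh
#' midpoints between the lower and upper size limits. The default 50-point
#' mesh on 30--85 mm gives a resolution of about 1 mm.
#'
#' @param L,U Lower and upper SVL limits (mm).
#' @param n Number of mesh points.
#' @return A list with `x` (midpoints) and `h` (cell width).
#' @export
ipm_mesh <- function(L = 30, U = 85, n = 50L) {
  h <- (U - L) / n
  list(x = L + h * (seq_len(n) - 0.5), h = h, L = L, U = U, n = n)
}

#' Survival-growth sub-kernel P
#'
#' `P[j, i] = G[j | i] * S(x_i)`: the probability that an individual of size
#' `x_i` survives the month and moves to size `y_j`. Because the growth
#' transition columns sum to one, each column of `P` sums exactly to the
#' survival probability of that size.
#'
#' @param mesh An [ipm_mesh()].
#' @param survival_fn Function mapping a vector of SVLs to monthly survival
#'   probabilities in \[0, 1\].
#' @param growth_fit A `growth_fit`.
#' @return A square matrix.
#' @export
build_P <- function(mesh, survival_fn, growth_fit) {
  s <- survival_fn(mesh$x)
  stopifnot(all(s >= 0), all(s <= 1))
  g <- growth_transition(mesh$x, growth_fit)
  sweep(g, 2, s, "*")
}

#' Fecundity sub-kernel F
#'
#' In breeding months, a mature female (SVL at or above the maturity
#' threshold) contributes `litter_mean * sex_ratio / n_breeding_months`
#' female recruits, distributed over offspring sizes by a discretised normal
#' neonate size distribution (normalised to sum to one). Outside the
#' breeding window F is identically zero, so summing F over the breeding
#' months of one year returns the full annual per-female recruitment.
#'
#' @param mesh An [ipm_mesh()].
#' @param month Calendar month (1-12).
#' @param maturity_svl Minimum reproductive SVL (mm).
#' @param litter_mean Annual litter size per reproductive female.
#' @param breeding_months Months with parturition.
#' @param neonate_mu,neonate_sd Neonate SVL distribution (mm).
#' @param sex_ratio Fraction of offspring that are female (female-based
#'   model).
#' @return A square matrix (zero outside the breeding window).
#' @export
build_F <- function(mesh, month, maturity_svl = 54, litter_mean = 4.1,
                    breeding_months = c(9, 10, 11, 12, 1),
                    neonate_mu = 35, neonate_sd = 2, sex_ratio = 0.5) {
  n <- mesh$n
  stopifnot(maturity_svl > mesh$L, maturity_svl < mesh$U)
  if (!(month %in% breeding_months)) {
    return(matrix(0, n, n))
  }
  outside <- stats::pnorm(mesh$L, neonate_mu, neonate_sd) +
    stats::pnorm(mesh$U, neonate_mu, neonate_sd, lower.tail = FALSE)
  if (outside > 0.01) {
    stop("more than 1% of the neonate size distribution falls outside the mesh")
  }
  phi <- stats::dnorm(mesh$x, neonate_mu, neonate_sd)
  phi <- phi / sum(phi)
  recruits <- ifelse(mesh$x >= maturity_svl,
                     litter_mean * sex_ratio / length(breeding_months), 0)
  outer(phi, recruits)
}

#' Combine size-dependent and environment-dependent survival
#'
#' The monthly survival entering the kernel merges the two fitted sources on
#' the logit scale: `logit(S) = logit(S_size(svl)) +
#' [logit(phi_cjs(env)) - logit(phi_cjs(mean env))]`. Under the average
#' environment the CJS offset vanishes and survival reduces to the
#' size-dependent (Gompertz) estimate; months hotter than average (with a
#' negative temperature coefficient) depress survival at every size.
#'
#' @param svl Vector of SVLs (mm).
#' @param month_env One-row data frame (or list) with the month's `tmax`,
#'   `precip` and `mean_svl`.
#' @param gompertz_fit A `gompertz_fit`.
#' @param cjs_fit A `cjs_fit` carrying its covariate standardisation.
#' @param growth_fit A `growth_fit` (for the SVL-to-age mapping).
#' @return Monthly survival probabilities, one per SVL.
#' @export
combine_survival <- function(svl, month_env, gompertz_fit, cjs_fit, growth_fit) {
  s_size <- suppressWarnings(survival_by_size(svl, gompertz_fit, growth_fit))
  env_df <- as.data.frame(month_env)[, c("tmax", "precip", "mean_svl")]
  phi_env <- monthly_survival_series(cjs_fit, env_df)
  # survival at average environment: all z-scores zero -> intercept only
  phi_bar <- inv_logit(unname(cjs_fit$beta_phi["intercept"]))
  offset <- logit(phi_env) - logit(phi_bar)
  inv_logit(logit(pmin(pmax(s_size, 1e-12), 1 - 1e-12)) + offset)
}

#' Assemble the IPM kernel for one month
#'
#' `K = P + F` with the month's environment-adjusted survival.
#'
#' @param mesh An [ipm_mesh()].
#' @param month Calendar month (1-12).
#' @param env One-row data frame with `tmax`, `precip`, `mean_svl`.
#' @param fits List with elements `growth` (`growth_fit`), `gompertz`
#'   (`gompertz_fit`), `cjs` (`cjs_fit`), `fecundity` (mean litter size or a
#'   `fecundity_fit`), and optional `maturity_svl`, `breeding_months`,
#'   `neonate_mu`, `neonate_sd`, `sex_ratio`.
#' @return An `ipm_kernel`: list with `mesh`, `P`, `F`, `K`, `month`, `env`.
#' @export
assemble_month <- function(mesh, month, env, fits) {
  litter <- if (inherits(fits$fecundity, "fecundity_fit")) {
    fits$fecundity$mean_litter
  } else {
    fits$fecundity
  }
  sfun <- function(x) combine_survival(x, env, fits$gompertz, fits$cjs, fits$growth)
  P <- build_P(mesh, sfun, fits$growth)
  F <- build_F(mesh, month,
               maturity_svl = fits$maturity_svl %||% 54,
               litter_mean = litter,
               breeding_months = fits$breeding_months %||% c(9, 10, 11, 12, 1),
               neonate_mu = fits$neonate_mu %||% 35,
               neonate_sd = fits$neonate_sd %||% 2,
               sex_ratio = fits$sex_ratio %||% 0.5)
  structure(list(mesh = mesh, P = P, F = F, K = P + F, month = month,
                 env = as.data.frame(env)),
            class = "ipm_kernel")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Yearly transition matrix from 12 monthly kernels
#'
#' Chronological left-product `A = K_12 %*% K_11 %*% ... %*% K_1`, so that
#' `n(t + 12) = A n(t)`.
#'
#' @param kernels List of exactly 12 `ipm_kernel`s (or plain matrices) in
#'   chronological order.
#' @return A square matrix.
#' @export
yearly_matrix <- function(kernels) {
  if (length(kernels) != 12) stop("a yearly matrix needs exactly 12 monthly kernels")
  mats <- lapply(kernels, function(k) if (inherits(k, "ipm_kernel")) k$K else k)
  A <- mats[[1]]
  for (i in 2:12) A <- mats[[i]] %*% A
  A
}

#' Dominant-eigenvalue demography of a projection matrix
#'
#' Computes the asymptotic population growth rate (the dominant eigenvalue)
#' by power iteration, together with the stable size distribution `w` (right
#' eigenvector, summing to one), the reproductive-value distribution `v`
#' (left eigenvector, normalised so `<v, w> = 1`), and, when mean monthly
#' sub-kernels are supplied, the net reproductive rate
#' `R0 = dominant eigenvalue of F (I - P)^-1` and the generation time
#' `T = log(R0) / log(lambda_monthly)` in months.
#'
#' @param A Nonnegative square matrix (primitivity is checked by verifying
#'   that a power of `A` is strictly positive).
#' @param P_mean,F_mean Optional mean monthly sub-kernels for `R0` and
#'   generation time.
#' @param monthly If `TRUE` the eigenvalue of `A` is already on the monthly
#'   scale; if `FALSE` (default) `A` is a yearly matrix and the monthly rate
#'   is its 12th root.
#' @param tol Power-iteration tolerance.
#' @return A `lambda_result`: `lambda`, `w`, `v`, `R0`, `T_gen` (months; `NA`
#'   with a flag when `lambda` is numerically 1), `T_bar` (mean age of
#'   mothers alternative, months).
#' @export
lambda_eigen <- function(A, P_mean = NULL, F_mean = NULL, monthly = FALSE,
                         tol = 1e-10) {
  stopifnot(all(A >= 0))
  n <- nrow(A)
  # primitivity check: (I + A)^(n-1) > 0 iff A irreducible; then some power
  # of A must be positive for primitivity
  M <- diag(n) + (A > 0)
  Mp <- M
  for (i in seq_len(ceiling(log2(n)) + 1)) Mp <- (Mp %*% Mp) > 0
  if (any(Mp == 0)) {
    bad <- which(rowSums(Mp) < n)[1]
    stop(sprintf("matrix is reducible: state %d is not reachable from all states", bad))
  }
  # power iteration on the shifted matrix A + cI: same eigenvectors, dominant
  # eigenvalue shifted by exactly c, but guaranteed aperiodic (so iteration
  # converges even for cyclic stage structures)
  shift <- max(colSums(A)) / 2 + tol
  As <- A + diag(shift, n)
  w <- rep(1 / n, n)
  lambda <- 1
  for (it in 1:50000) {
    w_new <- As %*% w
    lambda_new <- sum(w_new)
    w_new <- w_new / lambda_new
    if (max(abs(w_new - w)) < tol && abs(lambda_new - lambda) < tol) {
      w <- w_new; lambda <- lambda_new; break
    }
    w <- w_new; lambda <- lambda_new
  }
  lambda <- lambda - shift
  v <- rep(1 / n, n)
  for (it in 1:50000) {
    v_new <- drop(v %*% As)
    v_new <- v_new / sum(v_new)
    if (max(abs(v_new - v)) < tol) { v <- v_new; break }
    v <- v_new
  }
  w <- drop(w)
  v <- v / sum(v * w)  # <v, w> = 1

  R0 <- NA_real_; T_gen <- NA_real_; T_bar <- NA_real_
  if (!is.null(P_mean) && !is.null(F_mean)) {
    N <- solve(diag(n) - P_mean)
    R0 <- max(Re(eigen(F_mean %*% N, only.values = TRUE)$values))
    lam_m <- if (monthly) lambda else lambda^(1 / 12)
    if (abs(log(lam_m)) > 1e-6) {
      T_gen <- log(R0) / log(lam_m)
    }
    # mean age of mothers in the stable population (monthly kernel scale)
    lamA <- lam_m
    wm <- abs(Re(eigen(P_mean + F_mean)$vectors[, 1])); wm <- wm / sum(wm)
    vm <- abs(Re(eigen(t(P_mean + F_mean))$vectors[, 1]))
    vm <- vm / sum(vm * wm)
    T_bar <- lamA * sum(vm * wm) / sum(vm * (F_mean %*% wm))
  }
  structure(list(lambda = lambda, w = w, v = v, R0 = R0,
                 T_gen = T_gen, T_bar = T_bar,
                 lambda_flagged_unit = is.na(T_gen) && !is.na(R0)),
            class = "lambda_result")
}

#' @export
print.lambda_result <- function(x, ...) {
  cat(sprintf("lambda = %.4f", x$lambda))
  if (!is.na(x$R0)) cat(sprintf(", R0 = %.3f", x$R0))
  if (!is.na(x$T_gen)) cat(sprintf(", generation time = %.1f months", x$T_gen))
  else if (isTRUE(x$lambda_flagged_unit))
    cat(" (lambda ~ 1: log-ratio generation time undefined)")
  if (!is.na(x$T_bar)) cat(sprintf(", mean age of mothers = %.1f months", x$T_bar))
  cat("\n")
  invisible(x)
}

#' Perturbation (sensitivity and elasticity) analysis
#'
#' Kernel-level sensitivity `s(y, x) = v(y) w(x) / <v, w>` and elasticity
#' `e = (K / lambda) * s` of the yearly matrix, plus vital-rate elasticities
#' obtained by symmetric numeric perturbation (+/- 0.1%) of the survival,
#' growth, and fecundity components with the yearly matrix rebuilt each time.
#'
#' @param kernels List of 12 monthly `ipm_kernel`s.
#' @return A list with `sensitivity`, `elasticity` (matrices; elasticity sums
#'   to one), and `vital_rates` (named numeric: elasticity of lambda to
#'   proportional change in survival, growth spread, and fecundity).
#' @export
perturbation_analysis <- function(kernels) {
  A <- yearly_matrix(kernels)
  eig <- lambda_eigen(A)
  sens <- outer(eig$v, eig$w) / sum(eig$v * eig$w)
  elas <- (A / eig$lambda) * sens

  rel <- function(parts) {
    # rebuild the yearly matrix with P or F scaled by (1 +/- eps)
    eps <- 1e-3
    lam <- function(scaleP, scaleF) {
      mats <- lapply(kernels, function(k) scaleP * k$P + scaleF * k$F)
      lambda_eigen(Reduce(function(a, b) b %*% a, mats))$lambda
    }
    c(survival = (log(lam(1 + eps, 1)) - log(lam(1 - eps, 1))) / (2 * eps),
      fecundity = (log(lam(1, 1 + eps)) - log(lam(1, 1 - eps))) / (2 * eps))
  }
  list(sensitivity = sens, elasticity = elas, vital_rates = rel())
}

#' Per-month population growth rates and their geometric mean
#'
#' The monthly population growth metric is the dominant eigenvalue of each
#' month's kernel; its geometric mean over the series summarises the
#' population trajectory (1 = stationary).
#'
#' @param kernels List of monthly `ipm_kernel`s (or matrices).
#' @return A list with `lambda` (vector, one per month) and `geometric_mean`.
#' @export
monthly_lambda_series <- function(kernels) {
  lam <- vapply(kernels, function(k) {
    K <- if (inherits(k, "ipm_kernel")) k$K else k
    max(Mod(eigen(K, only.values = TRUE)$values))
  }, numeric(1))
  list(lambda = lam, geometric_mean = geometric_mean(lam))
}

#' Build the monthly kernel series for an environmental series
#'
#' @param env An `env_series` with `mean_svl` attached (see
#'   [monthly_covariates()]).
#' @param fits Fit list as for [assemble_month()].
#' @param mesh An [ipm_mesh()].
#' @return List of `ipm_kernel`s, one per row of `env`.
#' @export
kernel_series <- function(env, fits, mesh = ipm_mesh()) {
  lapply(seq_len(nrow(env)), function(i) {
    assemble_month(mesh, env$month[i], env[i, ], fits)
  })
}
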