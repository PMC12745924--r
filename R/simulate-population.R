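#' Simulate an individually marked population under monthly trapping
#'
#' Generates a capture table from known ground-truth parameters. Individuals
#' are born only in breeding months (some before the study starts, so the
#' initial population is age-structured), grow deterministically along a von
#' Bertalanffy trajectory from their own neonate SVL with an individual growth
#' coefficient `k_i ~ Normal(k_mean, k_sd)` truncated positive, die each month
#' with a Gompertz ageing hazard modulated on the logit-survival scale by the
#' (z-scored) environmental covariates, and are detected in each month they
#' are alive with a logit-linear detection probability. Only detected
#' individual-months appear in the capture table; the latent table retains
#' the truth needed for recovery tests.
#'
#' Monthly survival of individual `i` in month `t` is
#' `logit(S) = logit(exp(-H(a, a+1))) + beta_phi[2:4] . z_t`
#' where `H` is the integrated Gompertz hazard over one month of age; the
#' environmental effect is additive on the logit after the age term, and the
#' same convention is used by the kernel assembly, so simulator and fitters
#' share one model.
#'
#' @param params A [truth_params()] object.
#' @param n_individuals Number of individuals ever alive during the study.
#' @param n_months Number of monthly occasions; `env` must cover them.
#' @param env An `env_series` from [simulate_environment()].
#' @param age_structured If `TRUE` (default) some individuals are born before
#'   month 1; if `FALSE` all are present (age ~ 6 months) at month 1, which
#'   gives the pure Cormack-Jolly-Seber design used for detection tests.
#' @param unknown_sex_frac Fraction of individuals whose sex is recorded as
#'   `"U"` (unsexable juveniles); they are excluded from sex-specific fits.
#' @param seed Integer seed; defaults to the seed inside `params`.
#' @return A list with `captures` (the capture table: `id`, `session`, `sex`,
#'   `svl_mm`, `mass_g`, `tail_mm`, `tail_intact`), `latent` (truth per
#'   individual: birth/death month, `k`, `Linf`, neonate SVL) and the z-score
#'   `center`/`scale` applied to the covariates.
#' @export
simulate_population <- function(params, n_individuals, n_months, env,
                                age_structured = TRUE, unknown_sex_frac = 0.15,
                                seed = params$seed) {
  stopifnot(inherits(params, "truth_params"), nrow(env) >= n_months)
  env <- env[seq_len(n_months), ]
  set.seed(stage_seed(seed, "population"))

  zc <- zscore_covariates(env[, c("tmax", "precip")])
  z_tmax <- zc$z$tmax
  z_precip <- zc$z$precip

  n <- n_individuals
  sex <- sample(c("F", "M"), n, replace = TRUE)
  Linf <- ifelse(sex == "F", params$Linf_f, params$Linf_m)
  k <- stats::rnorm(n, params$k_mean, params$k_sd)
  while (any(k <= 0)) k[k <= 0] <- stats::rnorm(sum(k <= 0), params$k_mean, params$k_sd)
  l0 <- stats::rnorm(n, params$birth_svl_mean, params$birth_svl_sd)
  l0 <- pmin(pmax(l0, 25), params$birth_svl_mean + 3 * params$birth_svl_sd)

  if (age_structured) {
    # births in breeding months, up to 36 months before the study starts
    cand <- seq(-36L, n_months)
    cand <- cand[env_month(cand, env) %in% params$breeding_months]
    birth <- sample(cand, n, replace = TRUE)
  } else {
    birth <- rep(-5L, n)  # all ~6 months old at occasion 1
  }

  # per-individual monthly death simulation
  death <- integer(n)
  for (i in seq_len(n)) {
    m <- birth[i]
    repeat {
      age <- m - birth[i]
      s_age <- gompertz_survivorship(age + 1, params$gompertz_b0, params$gompertz_b1) /
        gompertz_survivorship(age, params$gompertz_b0, params$gompertz_b1)
      lg <- logit(pmin(pmax(s_age, 1e-12), 1 - 1e-12))
      if (m >= 1 && m <= n_months) {
        lg <- lg + params$beta_phi[2] * z_tmax[m] + params$beta_phi[3] * z_precip[m]
      }
      if (stats::runif(1) > inv_logit(lg)) { death[i] <- m; break }
      m <- m + 1L
      if (m > n_months + 1L) { death[i] <- NA_integer_; break }  # survives study
    }
  }

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    last <- if (is.na(death[i])) n_months else min(death[i], n_months)
    first <- max(birth[i], 1L)
    if (first > last) next
    months <- first:last
    p <- inv_logit(params$beta_p[1] +
                     params$beta_p[2] * z_tmax[months] +
                     params$beta_p[3] * z_precip[months])
    det <- stats::runif(length(months)) < p
    if (!any(det)) next
    mdet <- months[det]
    age <- mdet - birth[i]
    svl_true <- l0[i] + (Linf[i] - l0[i]) * (1 - exp(-k[i] * age))
    svl <- svl_true + stats::rnorm(length(mdet), 0, params$svl_obs_sd)
    tail_intact <- stats::runif(length(mdet)) < 0.85
    rows[[i]] <- data.frame(
      id = sprintf("ind%05d", i), session = mdet, sex = sex[i],
      svl_mm = svl,
      mass_g = 1.15e-5 * svl_true^3 + stats::rnorm(length(mdet), 0, 0.3),
      tail_mm = svl_true * 1.35 * ifelse(tail_intact, 1, 0.6) +
        stats::rnorm(length(mdet), 0, 2),
      tail_intact = as.integer(tail_intact))
  }
  captures <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(captures) <- NULL

  # unknown-sex animals: a fraction of individuals are recorded as U
  u <- stats::runif(n) < unknown_sex_frac
  captures$sex[captures$id %in% sprintf("ind%05d", which(u))] <- "U"

  latent <- data.frame(id = sprintf("ind%05d", seq_len(n)), sex = sex,
                       birth_month = birth, death_month = death,
                       k = k, Linf = Linf, birth_svl = l0)
  list(captures = captures, latent = latent,
       center = zc$center, scale = zc$scale)
}

# calendar month of an absolute month index, extrapolating the env calendar
# backwards for pre-study births
env_month <- function(idx, env) {
  ((env$month[1] - 1L + idx - 1L) %% 12L) + 1L
}

#' Simulate a gravid-female table
#'
#' Litter size is drawn from a Poisson regression on centred SVL with a log
#' link, truncated at one or more embryos and capped at the biological maximum
#' of eight offspring per litter.
#'
#' @param params A [truth_params()] object; `litter_mean` sets `exp(a)` at the
#'   mean SVL.
#' @param n Number of gravid females (>= 1).
#' @param b_svl Log-scale slope of litter size on SVL (per mm); default 0
#'   (constant litter size).
#' @param seed Integer seed.
#' @return A data frame with columns `svl_mm` (>= the maturity threshold) and
#'   `embryos` (integer in 1..8).
#' @export
simulate_gravid_females <- function(params, n, b_svl = 0, seed = params$seed) {
  stopifnot(n >= 1)
  set.seed(stage_seed(seed, "gravid"))
  svl <- stats::runif(n, params$maturity_svl, params$Linf_f - 2)
  mu <- params$litter_mean * exp(b_svl * (svl - mean(svl)))
  embryos <- stats::qpois(
    stats::runif(n, stats::ppois(0, mu), 1), mu)  # zero-truncated Poisson
  embryos <- pmin(embryos, 8L)
  data.frame(svl_mm = svl, embryos = as.integer(embryos))
}

#' Blank a fraction of SVL values to exercise imputation
#'
#' @param table A capture table.
#' @param fraction Fraction of SVL entries to blank, in (0, 0.1).
#' @param seed Integer seed.
#' @return The table with exactly `round(fraction * nrow)` SVL values set to
#'   `NA`; all other columns untouched.
#' @export
inject_missing_svl <- function(table, fraction, seed = 1L) {
  if (fraction < 0 || fraction >= 0.1) {
    stop("fraction must be in [0, 0.1)")
  }
  n_blank <- round(fraction * nrow(table))
  if (n_blank == 0) return(table)
  set.seed(stage_seed(seed, "missing_svl"))
  idx <- sample(nrow(table), n_blank)
  table$svl_mm[idx] <- NA_real_
  table
}
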