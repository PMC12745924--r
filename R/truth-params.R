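#' Ground-truth parameters for the synthetic demographic generator
#'
#' Bundles every parameter of the generative model that the synthetic-data
#' module simulates from: sex-specific von Bertalanffy growth (asymptotic SVL
#' `Linf_f`/`Linf_m`, monthly growth coefficient mean `k_mean` and
#' between-individual SD `k_sd`), the neonate size distribution, a Gompertz
#' ageing hazard (`gompertz_b0` log baseline hazard per month, `gompertz_b1`
#' hazard slope per month of age), logit-scale environmental effects on
#' monthly survival (`beta_phi`) and detection (`beta_p`), annual litter size,
#' and the breeding window. Downstream fitters are tested by their ability to
#' recover these values from simulated capture records.
#'
#' The defaults describe a small, fast-growing viviparous skink of seasonal
#' Neotropical savanna: neonates around 35 mm SVL, females maturing at 54 mm
#' in about 6 months, female asymptotic SVL 79 mm and male 71 mm, one litter
#' per female per year dropped during a September--January breeding window,
#' and monthly detection on the order of 0.25. The default litter size is
#' calibrated so that the reference population is stationary (geometric-mean
#' monthly population growth rate of 1) under the default environment.
#'
#' @param Linf_f,Linf_m Asymptotic SVL (mm) for females and males.
#' @param k_mean,k_sd Mean and between-individual SD of the monthly growth
#'   coefficient (1/month).
#' @param birth_svl_mean,birth_svl_sd Neonate SVL distribution (mm).
#' @param gompertz_b0 Log baseline mortality hazard (per month) at age 0.
#' @param gompertz_b1 Hazard slope per month of age (>= 0; senescence).
#' @param beta_phi Length-4 numeric: logit-survival coefficients for
#'   (intercept, tmax, precip, mean SVL). Covariates enter z-scored; the
#'   intercept is not used by the population simulator (the Gompertz term is
#'   the baseline) but defines baseline survival in pure CJS simulations.
#' @param beta_p Length-4 numeric: logit-detection coefficients, same order.
#' @param litter_mean Mean litter size (offspring per reproductive female per
#'   year), before the sex ratio is applied.
#' @param breeding_months Integer months (1-12) in which parturition occurs.
#' @param maturity_svl Minimum SVL (mm) of reproductive females.
#' @param svl_obs_sd Measurement SD (mm) of recorded SVL; 0 gives noise-free
#'   records.
#' @param seed Integer root seed.
#' @return An object of class `truth_params` (a validated list).
#' @export
truth_params <- function(Linf_f = 79, Linf_m = 71,
                         k_mean = 0.095, k_sd = 0.015,
                         birth_svl_mean = 35, birth_svl_sd = 2,
                         gompertz_b0 = -3.3, gompertz_b1 = 0.01,
                         beta_phi = c(0, -0.4, 0.1, 0),
                         beta_p = c(-1.1, 0, 0.15, 0),
                         litter_mean = 4.48,
                         breeding_months = c(9, 10, 11, 12, 1),
                         maturity_svl = 54,
                         svl_obs_sd = 1,
                         seed = 1L) {
  p <- list(Linf_f = Linf_f, Linf_m = Linf_m, k_mean = k_mean, k_sd = k_sd,
            birth_svl_mean = birth_svl_mean, birth_svl_sd = birth_svl_sd,
            gompertz_b0 = gompertz_b0, gompertz_b1 = gompertz_b1,
            beta_phi = beta_phi, beta_p = beta_p,
            litter_mean = litter_mean,
            breeding_months = as.integer(breeding_months),
            maturity_svl = maturity_svl,
            svl_obs_sd = svl_obs_sd, seed = as.integer(seed))
  validate_truth_params(p)
  class(p) <- "truth_params"
  p
}

#' Generative vital-rate set built directly from truth parameters
#'
#' Packages the ground-truth growth, mortality, environmental-survival and
#' fecundity parameters as the same fit objects the estimation stages
#' produce, so that kernels can be assembled from the generative model
#' itself. Used to define the reference (stationary) population and to test
#' that fitted kernels agree with generative ones.
#'
#' @param params A [truth_params()] object.
#' @param env The `env_series` whose covariate distribution defines the
#'   z-scoring (the environmental effects are anchored at its mean).
#' @param sigma_growth SD (mm) of the one-month growth transition used in the
#'   kernel; represents individual growth-coefficient variation plus
#'   measurement spread.
#' @return A fits list accepted by [assemble_month()] and [kernel_series()].
#' @export
truth_fits <- function(params, env, sigma_growth = 1.5) {
  stopifnot(inherits(params, "truth_params"))
  growth <- structure(list(
    Linf = params$Linf_f, k_fixed = params$k_mean,
    k_random_sd = params$k_sd,
    t0 = t0_for_birth_svl(params$Linf_f, params$k_mean, params$birth_svl_mean),
    sigma_resid = sigma_growth, conditional_r2 = 1,
    n_intervals = NA_integer_, n_individuals = NA_integer_, sex = "F",
    birth_svl = params$birth_svl_mean, method = "truth"), class = "growth_fit")
  gompertz <- structure(list(
    b0 = params$gompertz_b0, b1 = params$gompertz_b1, p = NA_real_,
    posterior = NULL, rhat = c(b0 = 1, b1 = 1), acceptance = NA_real_,
    n_individuals = NA_integer_), class = "gompertz_fit")
  zc <- zscore_covariates(as.data.frame(env)[, c("tmax", "precip")])
  mean_svl_bar <- if ("mean_svl" %in% names(env)) mean(env$mean_svl) else 60
  cjs <- structure(list(
    spec = list(phi_terms = c("tmax", "precip", "mean_svl"),
                p_terms = character(0)),
    beta_phi = c(intercept = 0, tmax = params$beta_phi[2],
                 precip = params$beta_phi[3], mean_svl = params$beta_phi[4]),
    beta_p = c(intercept = 0),
    loglik = NA_real_, n_params = 5L, aic = NA_real_, converged = TRUE,
    center = c(zc$center, mean_svl = mean_svl_bar),
    scale = c(zc$scale, mean_svl = 1)), class = "cjs_fit")
  list(growth = growth, gompertz = gompertz, cjs = cjs,
       fecundity = params$litter_mean,
       maturity_svl = params$maturity_svl,
       breeding_months = params$breeding_months,
       neonate_mu = params$birth_svl_mean,
       neonate_sd = max(params$birth_svl_sd, 0.5),
       sex_ratio = 0.5)
}

validate_truth_params <- function(p) {
  stopifnot(
    p$birth_svl_mean > 0,
    p$Linf_f > p$birth_svl_mean, p$Linf_m > p$birth_svl_mean,
    p$k_mean > 0, p$k_sd >= 0,
    p$gompertz_b1 >= 0,
    length(p$beta_phi) == 4, length(p$beta_p) == 4,
    p$litter_mean > 0,
    all(p$breeding_months %in% 1:12),
    p$maturity_svl > p$birth_svl_mean,
    p$svl_obs_sd >= 0
  )
  invisible(p)
}
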