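#' Default pipeline configuration
#'
#' @param out_dir Output directory for artifacts.
#' @param seed Root seed; every stage derives its own substream from it.
#' @return A named list understood by [run_pipeline()].
#' @export
default_config <- function(out_dir = tempfile("skinkipm_run_"), seed = 1L) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    synthetic = list(n_individuals = 800L, n_months = 120L,
                     n_gravid = 30L, missing_svl_fraction = 0.01),
    mesh = list(L = 30, U = 85, n = 50L),
    maturity_svl = 54,
    breeding_months = c(9, 10, 11, 12, 1),
    neonate_mu = 35, neonate_sd = 2, sex_ratio = 0.5,
    mcmc = list(gompertz = list(n_steps = 6000L, burn_in = 1500L,
                                thin = 10L, n_chains = 2L),
                fecundity = list(n_steps = 4000L, burn_in = 2000L,
                                 thin = 2L, n_chains = 4L)),
    spatial = NULL  # list(nx, ny, gradient, years) enables projection
  )
}

#' Validate a pipeline configuration
#'
#' Schema and cross-field checks; violations are reported, not thrown, so a
#' caller can surface all of them at once.
#'
#' @param config Configuration list (or path to a YAML file).
#' @return A list with `valid` (logical), `violations` and `warnings`
#'   (character vectors).
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- names(default_config())
  violations <- character(0)
  warns <- character(0)
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    warns <- c(warns, sprintf("unknown config key(s): %s",
                              paste(unknown, collapse = ", ")))
  }
  need <- c("seed", "out_dir", "synthetic", "mesh")
  miss <- setdiff(need, names(config))
  if (length(miss)) {
    violations <- c(violations, sprintf("missing key(s): %s",
                                        paste(miss, collapse = ", ")))
  }
  if (!is.null(config$mesh) && !is.null(config$maturity_svl)) {
    if (config$maturity_svl <= config$mesh$L ||
        config$maturity_svl >= config$mesh$U) {
      violations <- c(violations,
                      "maturity_svl must lie strictly inside the mesh bounds")
    }
  }
  if (!is.null(config$synthetic$missing_svl_fraction) &&
      (config$synthetic$missing_svl_fraction < 0 ||
       config$synthetic$missing_svl_fraction >= 0.1)) {
    violations <- c(violations, "missing_svl_fraction must be in [0, 0.1)")
  }
  if (!is.null(config$breeding_months) &&
      !all(config$breeding_months %in% 1:12)) {
    violations <- c(violations, "breeding_months must be calendar months 1-12")
  }
  list(valid = length(violations) == 0, violations = violations,
       warnings = warns)
}

#' Run the full demographic pipeline on synthetic data
#'
#' Executes, in order: data simulation, preprocessing (outlier blanking,
#' imputation, interval building, monthly covariates), the growth fit, the
#' Gompertz mortality fit, CJS model selection, the fecundity fit, monthly
#' kernel assembly with the population-growth series and its seasonal
#' decomposition, and (if configured) the spatial projection. Every stage
#' writes its artifact under `out_dir` and is recorded in a JSON manifest
#' with the seeds used and MD5 hashes of the files. A stage failure aborts
#' the run with the stage name; artifacts of completed stages persist.
#'
#' @param config Configuration list from [default_config()] (or a YAML path).
#' @param truth Optional [truth_params()] (defaults to the calibrated
#'   stationary reference population).
#' @return The manifest (list), invisibly written to
#'   `out_dir/manifest.json`; carries `fits`, `lambda` and `decomposition`
#'   entries for programmatic use.
#' @export
run_pipeline <- function(config = default_config(), truth = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  chk <- validate_config(config)
  if (!chk$valid) {
    stop("invalid config: ", paste(chk$violations, collapse = "; "))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  if (is.null(truth)) truth <- truth_params(seed = seed)
  manifest <- list(package = "skinkipm",
                   version = as.character(utils::packageVersion("skinkipm")),
                   seed = seed, stages = list())
  t_start <- Sys.time()

  record <- function(stage, files) {
    manifest$stages[[stage]] <<- list(
      files = as.list(files),
      md5 = as.list(unname(tools::md5sum(files))))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # --- synthetic data -------------------------------------------------------
  sim <- run_stage("synthetic_data", {
    env <- simulate_environment(config$synthetic$n_months, seed = seed)
    pop <- simulate_population(truth, config$synthetic$n_individuals,
                               config$synthetic$n_months, env, seed = seed)
    gravid <- simulate_gravid_females(truth, config$synthetic$n_gravid,
                                      seed = seed)
    captures <- inject_missing_svl(pop$captures,
                                   config$synthetic$missing_svl_fraction,
                                   seed = seed)
    f_cap <- file.path(config$out_dir, "captures.csv")
    f_env <- file.path(config$out_dir, "environment.csv")
    f_grav <- file.path(config$out_dir, "gravid.csv")
    utils::write.csv(captures, f_cap, row.names = FALSE)
    utils::write.csv(env, f_env, row.names = FALSE)
    utils::write.csv(gravid, f_grav, row.names = FALSE)
    record("synthetic_data", c(f_cap, f_env, f_grav))
    list(captures = captures, env = env, gravid = gravid, latent = pop$latent)
  })

  # --- preprocess -----------------------------------------------------------
  prep <- run_stage("preprocess", {
    tab <- flag_svl_outliers(sim$captures)
    tab <- impute_svl(tab, seed = seed)
    intervals <- build_recapture_intervals(tab)
    cov <- monthly_covariates(tab, sim$env)
    f_int <- file.path(config$out_dir, "intervals.csv")
    f_cov <- file.path(config$out_dir, "covariates.csv")
    utils::write.csv(as.data.frame(intervals), f_int, row.names = FALSE)
    utils::write.csv(cov, f_cov, row.names = FALSE)
    f_q <- file.path(config$out_dir, "quality.json")
    jsonlite::write_json(
      list(n_imputed = length(attr(tab, "imputed_rows")),
           n_outliers_blanked = length(attr(tab, "outlier_rows")),
           n_unknown_sex_captures = attr(intervals, "n_excluded_unknown_sex"),
           n_intervals_flagged_linf = sum(intervals$flag_linf)),
      f_q, auto_unbox = TRUE)
    record("preprocess", c(f_int, f_cov, f_q))
    list(table = tab, intervals = intervals, covariates = cov)
  })

  # --- growth ---------------------------------------------------------------
  growth_f <- run_stage("growth", {
    g <- fit_fabens_mixed(prep$intervals, sex = "F",
                          birth_svl = config$neonate_mu)
    f_g <- file.path(config$out_dir, "growth_fit.json")
    jsonlite::write_json(unclass(g), f_g, auto_unbox = TRUE, digits = NA)
    record("growth", f_g)
    g
  })

  # --- survival: Gompertz ---------------------------------------------------
  gomp <- run_stage("survival_gompertz", {
    ages <- gompertz_age_table(prep$table[prep$table$sex != "U", ], growth_f)
    fit <- fit_gompertz(ages, mcmc = config$mcmc$gompertz, seed = seed)
    f <- file.path(config$out_dir, "gompertz_fit.json")
    jsonlite::write_json(list(b0 = fit$b0, b1 = fit$b1, p = fit$p,
                              rhat = as.list(fit$rhat)),
                         f, auto_unbox = TRUE, digits = NA)
    utils::write.csv(as.data.frame(fit$posterior),
                     file.path(config$out_dir, "gompertz_posterior.csv"),
                     row.names = FALSE)
    record("survival_gompertz",
           c(f, file.path(config$out_dir, "gompertz_posterior.csv")))
    fit
  })

  # --- survival: CJS --------------------------------------------------------
  cjs <- run_stage("survival_cjs", {
    h <- capture_histories(prep$table, config$synthetic$n_months)
    sel <- fit_all_and_select(h, prep$covariates)
    f_tab <- file.path(config$out_dir, "cjs_aic_table.csv")
    utils::write.csv(sel$table, f_tab, row.names = FALSE)
    f_best <- file.path(config$out_dir, "cjs_best.json")
    jsonlite::write_json(
      list(phi_terms = sel$best$spec$phi_terms, p_terms = sel$best$spec$p_terms,
           beta_phi = as.list(sel$best$beta_phi),
           beta_p = as.list(sel$best$beta_p), aic = sel$best$aic),
      f_best, auto_unbox = TRUE, digits = NA)
    record("survival_cjs", c(f_tab, f_best))
    sel
  })

  # --- fecundity ------------------------------------------------------------
  fec <- run_stage("fecundity", {
    if (is.null(sim$gravid) || nrow(sim$gravid) == 0) stop("no gravid-female data")
    fits <- list(
      poisson = fit_litter_model(sim$gravid, "poisson",
                                 mcmc = config$mcmc$fecundity, seed = seed),
      negbinomial = fit_litter_model(sim$gravid, "negbinomial",
                                     mcmc = config$mcmc$fecundity, seed = seed))
    loo <- compare_loo(fits)
    best <- fits[[loo$model[1]]]
    f_loo <- file.path(config$out_dir, "fecundity_loo.csv")
    utils::write.csv(loo, f_loo, row.names = FALSE)
    f_fit <- file.path(config$out_dir, "fecundity_fit.json")
    jsonlite::write_json(list(family = best$family, alpha = best$alpha,
                              beta_svl = best$beta_svl,
                              mean_litter = best$mean_litter),
                         f_fit, auto_unbox = TRUE, digits = NA)
    record("fecundity", c(f_loo, f_fit))
    best
  })

  # --- IPM ------------------------------------------------------------------
  fits <- list(growth = growth_f, gompertz = gomp, cjs = cjs$best,
               fecundity = fec,
               maturity_svl = config$maturity_svl,
               breeding_months = config$breeding_months,
               neonate_mu = config$neonate_mu, neonate_sd = config$neonate_sd,
               sex_ratio = config$sex_ratio)
  mesh <- ipm_mesh(config$mesh$L, config$mesh$U, config$mesh$n)
  ipm <- run_stage("ipm_core", {
    kernels <- kernel_series(prep$covariates, fits, mesh)
    lam <- monthly_lambda_series(kernels)
    f_lam <- file.path(config$out_dir, "lambda_series.csv")
    utils::write.csv(data.frame(month_index = prep$covariates$month_index,
                                lambda = lam$lambda),
                     f_lam, row.names = FALSE)
    record("ipm_core", f_lam)
    list(kernels = kernels, lambda = lam)
  })

  # --- decomposition --------------------------------------------------------
  dec <- run_stage("ts_decompose", {
    d <- decompose_series(ipm$lambda$lambda)
    shares <- variance_shares(d)
    f_dec <- file.path(config$out_dir, "lambda_decomposition.csv")
    utils::write.csv(as.data.frame(d), f_dec, row.names = FALSE)
    f_sh <- file.path(config$out_dir, "lambda_shares.json")
    jsonlite::write_json(as.list(shares), f_sh, auto_unbox = TRUE, digits = NA)
    record("ts_decompose", c(f_dec, f_sh))
    list(decomposition = d, shares = shares)
  })

  # --- optional spatial projection -----------------------------------------
  field <- NULL
  if (!is.null(config$spatial)) {
    field <- run_stage("spatial_projection", {
      sp <- config$spatial
      stack <- simulate_climate_rasters(sp$nx, sp$ny,
                                        n_months = 12 * length(sp$years),
                                        gradient = sp$gradient, seed = seed,
                                        start_month = 1L)
      fld <- project_lambda(stack, fits, sp$years, scenario = "synthetic",
                            mesh = mesh)
      f_map <- file.path(config$out_dir, "lambda_field_mean.csv")
      utils::write.csv(fld$mean[[1]], f_map, row.names = FALSE)
      record("spatial_projection", f_map)
      fld
    })
  }

  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  manifest$fits <- fits
  manifest$lambda <- ipm$lambda
  manifest$decomposition <- dec
  manifest$lambda_field <- field
  manifest$latent <- sim$latent
  json <- manifest
  json$fits <- NULL; json$lambda_field <- NULL; json$latent <- NULL
  json$lambda <- list(geometric_mean = ipm$lambda$geometric_mean)
  json$decomposition <- as.list(dec$shares)
  jsonlite::write_json(json, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
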