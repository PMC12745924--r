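# brute-force CJS likelihood for one history: enumerate the latent last-alive
# occasion d; the animal survives f..d, dies in (d, d+1) (or survives past T)
cjs_brute_one <- function(h, phi, p) {
  T <- length(h)
  f <- which(h == 1)[1]
  l <- max(which(h == 1))
  tot <- 0
  for (d in l:T) {
    pr <- 1
    if (d > f) pr <- prod(phi[f:(d - 1)])
    if (d < T) pr <- pr * (1 - phi[d])
    if (d > f) {
      mid <- (f + 1):d
      pr <- pr * prod(ifelse(h[mid] == 1, p[mid], 1 - p[mid]))
    }
    tot <- tot + pr
  }
  tot
}

const_cov <- function(T) data.frame(tmax = rep(0, T), precip = 0, mean_svl = 0)
icpt_spec <- list(phi_terms = character(0), p_terms = character(0))

test_that("candidate model set is the exact 8 x 8 covariate cross", {
  specs <- enumerate_models()
  expect_length(specs, 64)
  labels <- vapply(specs, function(s)
    paste(paste(s$phi_terms, collapse = "+"), "|",
          paste(s$p_terms, collapse = "+")), character(1))
  expect_identical(anyDuplicated(labels), 0L)
  expect_true(any(labels == " | "))  # intercept-only / intercept-only
  sizes <- vapply(specs, function(s) length(s$phi_terms) + length(s$p_terms),
                  integer(1))
  expect_identical(sum(sizes == 6), 1L)  # single global model
})

test_that("CJS likelihood matches hand-computed histories", {
  # 1,1,1 with p = 1, phi = 0.8: likelihood phi^2 = 0.64
  b <- c(qlogis(0.8), qlogis(1 - 1e-12))
  ll <- cjs_loglik(matrix(c(1, 1, 1), 1), const_cov(3), icpt_spec, b)
  expect_equal(exp(ll), 0.64, tolerance = 1e-6)

  # 1,0,1 with phi = 0.8, p = 0.5: phi (1-p) phi p = 0.16
  b <- c(qlogis(0.8), qlogis(0.5))
  ll <- cjs_loglik(matrix(c(1, 0, 1), 1), const_cov(3), icpt_spec, b)
  expect_equal(exp(ll), 0.16, tolerance = 1e-12)

  expect_error(cjs_loglik(matrix(0, 1, 3), const_cov(3), icpt_spec, b),
               "no capture")
})

test_that("chi-recursion likelihood equals latent-state enumeration on all short histories", {
  set.seed(4)
  for (T in 4:6) {
    cov <- data.frame(tmax = rnorm(T), precip = rnorm(T), mean_svl = rnorm(T))
    spec <- list(phi_terms = c("tmax", "precip"), p_terms = "mean_svl")
    beta <- c(0.8, -0.5, 0.3, -0.4, 0.6)
    xphi <- cbind(1, cov$tmax, cov$precip)
    xp <- cbind(1, cov$mean_svl)
    phi <- plogis(drop(xphi %*% beta[1:3]))
    p <- plogis(drop(xp %*% beta[4:5]))
    # all histories with at least one capture
    hs <- as.matrix(expand.grid(rep(list(0:1), T)))
    hs <- hs[rowSums(hs) > 0, ]
    for (r in seq_len(nrow(hs))) {
      h <- hs[r, ]
      ll <- cjs_loglik(matrix(h, 1), cov, spec, beta)
      expect_equal(ll, log(cjs_brute_one(h, phi, p)), tolerance = 1e-12)
    }
  }
})

test_that("grouped sufficient-statistic likelihood agrees with the per-history form", {
  set.seed(5)
  T <- 12
  cov <- data.frame(tmax = rnorm(T), precip = rnorm(T), mean_svl = rnorm(T))
  h <- matrix(rbinom(40 * T, 1, 0.4), 40, T)
  h <- h[rowSums(h) > 0, ]
  spec <- list(phi_terms = "tmax", p_terms = c("precip", "mean_svl"))
  beta <- c(1.2, -0.4, -0.8, 0.2, 0.1)
  g <- skinkipm:::cjs_groups(h)
  expect_equal(skinkipm:::cjs_loglik_grouped(g, cov, spec, beta),
               cjs_loglik(h, cov, spec, beta), tolerance = 1e-10)
  # individual order invariance
  expect_equal(cjs_loglik(h[sample(nrow(h)), ], cov, spec, beta),
               cjs_loglik(h, cov, spec, beta), tolerance = 1e-12)
})

test_that("model selection honours AIC arithmetic and finds null models", {
  tp <- truth_params(gompertz_b0 = -3.2, gompertz_b1 = 0,
                     beta_phi = c(0, 0, 0, 0), beta_p = c(-0.8, 0, 0, 0),
                     seed = 41)
  env <- simulate_environment(30, trend = 0, seed = 41)
  sim <- simulate_population(tp, 500, 30, env, age_structured = FALSE,
                             unknown_sex_frac = 0, seed = 41)
  h <- capture_histories(sim$captures, 30)
  cov <- monthly_covariates(sim$captures, env)
  sel <- fit_all_and_select(h, cov)
  expect_equal(sel$table$aic, -2 * sel$table$loglik + 2 * sel$table$n_params)
  null_row <- which(sel$table$phi_terms == "" & sel$table$p_terms == "")
  expect_lt(sel$table$delta_aic[null_row], 4)  # constant truth: null near top
})

test_that("standardising covariates leaves the maximised likelihood unchanged", {
  tp <- truth_params(gompertz_b0 = -3.2, gompertz_b1 = 0,
                     beta_phi = c(0, -0.4, 0, 0), beta_p = c(-0.8, 0, 0, 0),
                     seed = 43)
  env <- simulate_environment(30, trend = 0, seed = 43)
  sim <- simulate_population(tp, 400, 30, env, age_structured = FALSE,
                             unknown_sex_frac = 0, seed = 43)
  h <- capture_histories(sim$captures, 30)
  cov <- monthly_covariates(sim$captures, env)[, c("tmax", "precip", "mean_svl")]
  spec <- list(phi_terms = "tmax", p_terms = character(0))
  zcov <- as.data.frame(scale(cov))
  ccov <- as.data.frame(scale(cov, scale = FALSE))  # centred, original scale
  f_std <- fit_cjs(h, zcov, spec, n_starts = 3)
  f_ctr <- fit_cjs(h, ccov, spec, n_starts = 3)
  expect_equal(f_ctr$loglik, f_std$loglik, tolerance = 1e-6)

  # exact likelihood invariance: map the standardised optimum to the raw
  # covariate scale and evaluate the likelihood there
  m <- mean(cov$tmax); s <- sd(cov$tmax)
  b_raw <- c(f_std$beta_phi["intercept"] - f_std$beta_phi["tmax"] * m / s,
             f_std$beta_phi["tmax"] / s, f_std$beta_p)
  expect_equal(cjs_loglik(h, cov, spec, unname(b_raw)), f_std$loglik,
               tolerance = 1e-10)
})

test_that("monthly survival series responds to covariates as the link dictates", {
  T <- 24
  cov <- data.frame(tmax = seq(-2, 2, length.out = T), precip = 0, mean_svl = 0)
  fit <- structure(list(spec = icpt_spec,
                        beta_phi = c(intercept = 1.2), beta_p = c(intercept = 0)),
                   class = "cjs_fit")
  s <- monthly_survival_series(fit, cov)
  expect_equal(s, rep(plogis(1.2), T))

  fit2 <- structure(list(spec = list(phi_terms = "tmax", p_terms = character(0)),
                         beta_phi = c(intercept = 1.2, tmax = -0.5),
                         beta_p = c(intercept = 0)),
                    class = "cjs_fit")
  s2 <- monthly_survival_series(fit2, cov)
  expect_true(all(diff(s2) < 0))  # antitone in rising temperature
})
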