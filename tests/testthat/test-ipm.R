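fixed_growth <- structure(list(Linf = 79, k_fixed = 0.095,
                               t0 = -log(79 / 44) / 0.095, sigma_resid = 1.5,
                               k_random_sd = 0, birth_svl = 35,
                               method = "truth"),
                          class = "growth_fit")

test_that("P sub-kernel column sums equal size-specific survival and conserve cohorts", {
  mesh <- ipm_mesh()
  sfun <- function(x) 0.9 + 0.05 * sin(x / 10)
  P <- build_P(mesh, sfun, fixed_growth)
  expect_equal(colSums(P), sfun(mesh$x), tolerance = 1e-12)

  # conservation oracle: survivors of any cohort are preserved exactly
  set.seed(1)
  n0 <- runif(mesh$n)
  expect_equal(sum(P %*% n0) * mesh$h, sum(sfun(mesh$x) * n0) * mesh$h,
               tolerance = 1e-10)

  # S = 1 with near-deterministic, near-zero growth: P approaches identity
  g0 <- fixed_growth; g0$sigma_resid <- 1e-10; g0$k_fixed <- 1e-10
  P1 <- build_P(mesh, function(x) rep(1, length(x)), g0)
  expect_equal(P1, diag(mesh$n), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("F sub-kernel obeys the breeding window, maturity threshold, and annual budget", {
  mesh <- ipm_mesh()
  expect_identical(build_F(mesh, 6), matrix(0, 50, 50))  # June: no reproduction

  Fb <- build_F(mesh, 10, litter_mean = 4.48)
  immature <- mesh$x < 54
  expect_true(all(Fb[, immature] == 0))
  expect_true(all(Fb[, !immature] >= 0))

  # sum over the five breeding months: full annual female recruitment
  tot <- Reduce(`+`, lapply(c(9, 10, 11, 12, 1), function(m)
    build_F(mesh, m, litter_mean = 4.48)))
  mature_col <- which(!immature)[1]
  expect_equal(sum(tot[, mature_col]), 4.48 * 0.5, tolerance = 1e-10)

  # neonate mass escaping the mesh is an error
  expect_error(build_F(mesh, 10, neonate_mu = 31, neonate_sd = 3), "outside the mesh")
})

test_that("combined survival anchors at the mean environment and matches the generator", {
  ts <- truth_fit_set()
  env <- ts$env
  mean_env <- data.frame(tmax = mean(env$tmax), precip = mean(env$precip),
                         mean_svl = 60)
  svl <- seq(36, 75, by = 5)
  s_comb <- combine_survival(svl, mean_env, ts$fits$gompertz, ts$fits$cjs,
                             ts$fits$growth)
  s_size <- survival_by_size(svl, ts$fits$gompertz, ts$fits$growth)
  expect_equal(s_comb, s_size, tolerance = 1e-9)

  # a hotter-than-average month depresses survival at every size (beta_tmax < 0)
  hot <- mean_env; hot$tmax <- hot$tmax + 2
  expect_true(all(combine_survival(svl, hot, ts$fits$gompertz, ts$fits$cjs,
                                   ts$fits$growth) < s_size))

  # generative identity: equals the simulator's survival rule exactly
  z <- (env$tmax[5] - mean(env$tmax)) / sd(env$tmax)
  zp <- (env$precip[5] - mean(env$precip)) / sd(env$precip)
  a <- age_from_length(50, ts$tp$Linf_f, ts$tp$k_mean,
                       -log(79 / 44) / ts$tp$k_mean)
  s_gen <- plogis(qlogis(gompertz_survivorship(a + 1, ts$tp$gompertz_b0, ts$tp$gompertz_b1) /
                           gompertz_survivorship(a, ts$tp$gompertz_b0, ts$tp$gompertz_b1)) +
                    ts$tp$beta_phi[2] * z + ts$tp$beta_phi[3] * zp)
  s_pkg <- combine_survival(50, env[5, c("tmax", "precip")] |>
                              transform(mean_svl = 60),
                            ts$fits$gompertz, ts$fits$cjs, ts$fits$growth)
  expect_equal(s_pkg, s_gen, tolerance = 1e-9)
})

test_that("monthly kernels reduce to P outside the breeding season and stay nonnegative", {
  ts <- truth_fit_set()
  mesh <- ipm_mesh()
  k_jun <- assemble_month(mesh, 6, ts$env[7, ] |> transform(mean_svl = 60), ts$fits)
  expect_identical(k_jun$K, k_jun$P)
  k_oct <- assemble_month(mesh, 10, ts$env[11, ] |> transform(mean_svl = 60), ts$fits)
  expect_true(all(k_oct$K >= 0))
  expect_true(any(k_oct$F > 0))
})

test_that("yearly matrix is the chronological kernel product", {
  n <- 6
  set.seed(2)
  mats <- lapply(1:12, function(i) matrix(runif(n * n, 0, 0.3), n, n))
  A <- yearly_matrix(mats)
  v <- runif(n)
  stepped <- Reduce(function(x, M) M %*% x, mats, init = v)
  expect_equal(drop(A %*% v), drop(stepped), tolerance = 1e-12)

  expect_equal(yearly_matrix(rep(list(diag(n)), 12)), diag(n))
  d1 <- lapply(1:12, function(i) diag(seq(0.5, 1, length.out = n) * (1 + i / 100)))
  expect_equal(yearly_matrix(d1), Reduce(`*`, d1))
  expect_error(yearly_matrix(mats[1:11]), "12")
})

test_that("eigen demography matches closed forms and a dense solver", {
  # 2x2 juvenile/adult loop: lambda = sqrt(s f)
  s <- 0.7; f <- 1.9
  A <- matrix(c(0, s, f, 0), 2, 2)
  r <- lambda_eigen(A)
  expect_equal(r$lambda, sqrt(s * f), tolerance = 1e-9)

  set.seed(3)
  for (i in 1:5) {
    M <- matrix(runif(64), 8, 8)
    expect_equal(lambda_eigen(M)$lambda, max(Re(eigen(M)$values)),
                 tolerance = 1e-8)
  }

  # identity matrix: lambda 1, generation time flagged undefined
  r1 <- lambda_eigen(diag(2) + 1e-9, P_mean = diag(2) * 0.5,
                     F_mean = matrix(0.25, 2, 2))
  expect_true(is.na(r1$T_gen))
  expect_true(r1$lambda_flagged_unit)

  expect_error(lambda_eigen(diag(c(1, 2))), "reducible")
})

test_that("elasticities sum to one and sensitivity matches finite differences", {
  ts <- truth_fit_set()
  mesh <- ipm_mesh()
  env12 <- ts$env[2:13, ] |> transform(mean_svl = 60)
  kernels <- kernel_series(env12, ts$fits, mesh)
  pa <- perturbation_analysis(kernels)
  expect_equal(sum(pa$elasticity), 1, tolerance = 1e-8)

  A <- yearly_matrix(kernels)
  lam <- lambda_eigen(A)$lambda
  h <- 1e-6
  for (idx in list(c(3, 40), c(10, 25), c(25, 45))) {
    Ap <- A; Ap[idx[1], idx[2]] <- Ap[idx[1], idx[2]] + h
    num <- (lambda_eigen(Ap)$lambda - lam) / h
    expect_equal(num, pa$sensitivity[idx[1], idx[2]], tolerance = 1e-3)
  }

  # survival-dominated dynamics: survival elasticity exceeds fecundity
  expect_gt(pa$vital_rates["survival"], pa$vital_rates["fecundity"])
})

test_that("lambda is insensitive to mesh refinement and monotone in kernel entries", {
  ts <- truth_fit_set()
  env12 <- ts$env[2:13, ] |> transform(mean_svl = 60)
  lam50 <- lambda_eigen(yearly_matrix(kernel_series(env12, ts$fits, ipm_mesh(n = 50))))$lambda
  lam500 <- lambda_eigen(yearly_matrix(kernel_series(env12, ts$fits, ipm_mesh(n = 500))))$lambda
  expect_lt(abs(lam50 - lam500) / lam500, 0.01)

  # monotone dominant eigenvalue
  kernels <- kernel_series(env12, ts$fits, ipm_mesh())
  A <- yearly_matrix(kernels)
  lam <- lambda_eigen(A)$lambda
  A2 <- A * 1.001
  expect_gt(lambda_eigen(A2)$lambda, lam)
})

test_that("monthly lambda series is constant under constant environment", {
  ts <- truth_fit_set()
  env_const <- ts$env[2:13, ]
  env_const$tmax <- mean(ts$env$tmax)
  env_const$precip <- mean(ts$env$precip)
  env_const$mean_svl <- 60
  kernels <- kernel_series(env_const, ts$fits)
  lam <- monthly_lambda_series(kernels)
  breeding <- env_const$month %in% ts$tp$breeding_months
  expect_lt(diff(range(lam$lambda[breeding])), 1e-10)
  expect_lt(diff(range(lam$lambda[!breeding])), 1e-10)
  expect_equal(lam$geometric_mean, exp(mean(log(lam$lambda))))
  expect_equal(skinkipm:::geometric_mean(rep(0.97, 30)), 0.97)
})
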