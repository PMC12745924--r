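test_that("environment simulator produces exact periodicity, determinism, and a recoverable trend", {
  # noise-free seasonal series is exactly periodic with period 12
  e <- simulate_environment(48, seasonal_amp = 3, trend = 0, noise_sd = 0, seed = 1)
  expect_equal(e$tmax[1:36], e$tmax[13:48])
  expect_true(all(e$precip >= 0))
  expect_equal(e$month_index, 1:48)

  # same seed -> identical series; different seed -> different noise
  e1 <- simulate_environment(36, seed = 9)
  e2 <- simulate_environment(36, seed = 9)
  e3 <- simulate_environment(36, seed = 10)
  expect_identical(e1, e2)
  expect_false(identical(e1$tmax, e3$tmax))

  # pure linear ramp: OLS slope recovers the trend (2 C/decade = 2/120 per month)
  er <- simulate_environment(120, seasonal_amp = 0, trend = 2, noise_sd = 0, seed = 1)
  slope <- unname(coef(lm(er$tmax ~ er$month_index))[2])
  expect_equal(slope, 2 / 120, tolerance = 1e-9)

  expect_error(simulate_environment(12), "24")
})

test_that("population simulator respects birth/death bounds and the growth identity", {
  pp <- perfect_population(n = 50, months = 30)
  cap <- pp$sim$captures
  lat <- pp$sim$latent

  # perfect detection, no deaths: every alive study month appears
  for (id in unique(cap$id)) {
    b <- lat$birth_month[lat$id == id]
    expect_identical(sort(cap$session[cap$id == id]),
                     seq(max(b, 1L), 30L))
  }

  # SVL sequences satisfy the Fabens growth identity exactly between captures
  d <- cap[cap$id == cap$id[1], ]
  d <- d[order(d$session), ]
  k_i <- lat$k[lat$id == d$id[1]]
  Linf_i <- lat$Linf[lat$id == d$id[1]]
  for (j in seq_len(nrow(d) - 1)) {
    pred <- predict_length(d$svl_mm[j], Linf_i, k_i, d$session[j + 1] - d$session[j])
    expect_equal(d$svl_mm[j + 1], pred, tolerance = 1e-9)
  }

  # no detection before birth or after death, with deaths switched on
  tp <- truth_params(seed = 3)
  env <- simulate_environment(48, seed = 3)
  sim <- simulate_population(tp, 300, 48, env, seed = 3)
  m <- merge(sim$captures, sim$latent[, c("id", "birth_month", "death_month")], by = "id")
  expect_true(all(m$session >= m$birth_month))
  expect_true(all(is.na(m$death_month) | m$session <= m$death_month))

  # births restricted to breeding months
  bm <- ((env$month[1] - 1 + sim$latent$birth_month - 1) %% 12) + 1
  expect_true(all(bm %in% tp$breeding_months))
})

test_that("simulated cohort survivorship matches the closed-form Gompertz", {
  # S(12) = exp{(e^-3 / 0.1) (1 - e^1.2)} = 0.315 for b0 = -3, b1 = 0.1
  tp <- truth_params(gompertz_b0 = -3, gompertz_b1 = 0.1,
                     beta_phi = c(0, 0, 0, 0), beta_p = c(30, 0, 0, 0),
                     svl_obs_sd = 0, seed = 21)
  env <- simulate_environment(60, seed = 21)
  sim <- simulate_population(tp, 10000, 60, env, seed = 21)
  lat <- sim$latent
  lat <- lat[lat$birth_month <= 60 - 13, ]  # room to observe 12 months of life
  lived12 <- is.na(lat$death_month) | (lat$death_month - lat$birth_month >= 12)
  expected <- exp(exp(-3) / 0.1 * (1 - exp(0.1 * 12)))
  expect_equal(expected, 0.315, tolerance = 1e-3)  # frozen closed-form value
  mc_se <- sqrt(expected * (1 - expected) / nrow(lat))
  expect_lt(abs(mean(lived12) - expected), 4 * mc_se)
})

test_that("gravid-female generator matches the capped truncated-Poisson mean", {
  tp <- truth_params(seed = 5)
  g <- simulate_gravid_females(tp, 10000, b_svl = 0, seed = 5)
  expect_true(all(g$embryos >= 1 & g$embryos <= 8))
  expect_true(all(g$svl_mm >= tp$maturity_svl))
  # oracle: E[min(X, 8)] for X ~ zero-truncated Poisson(litter_mean)
  mu <- tp$litter_mean
  k <- 1:200
  pk <- dpois(k, mu) / (1 - dpois(0, mu))
  expected <- sum(pmin(k, 8) * pk)
  expect_lt(abs(mean(g$embryos) - expected), 4 * sd(g$embryos) / sqrt(nrow(g)))
  # seeded repeatability
  expect_identical(g, simulate_gravid_females(tp, 10000, b_svl = 0, seed = 5))
})

test_that("climate rasters carry the imposed gradient and round-trip through TIFF", {
  st0 <- simulate_climate_rasters(4, 3, 24, gradient = 0, seed = 2)
  base <- simulate_environment(24, seed = 2)
  for (ix in 1:4) for (iy in 1:3) {
    expect_equal(pixel_series(st0, ix, iy)$tmax, base$tmax)
  }

  st <- simulate_climate_rasters(5, 3, 24, gradient = 0.5, seed = 2)
  mt <- apply(st$tmax, 2, mean)  # mean tmax per column
  expect_true(all(diff(mt) > 0))

  dir <- file.path(tempdir(), "stack_rt")
  write_raster_stack(st, dir)
  st2 <- read_raster_stack(dir)
  span <- diff(range(st$tmax))
  expect_lt(max(abs(st2$tmax - st$tmax)), span * 1e-6)  # float32 precision
  expect_equal(st2$transform, st$transform)
  unlink(dir, recursive = TRUE)
})

test_that("SVL blanking hits the exact count and is reproducible", {
  tab <- data.frame(id = sprintf("i%04d", 1:1400), session = 1L, sex = "F",
                    svl_mm = runif(1400, 35, 79), mass_g = 1, tail_mm = 1,
                    tail_intact = 1L)
  out <- inject_missing_svl(tab, 0.01, seed = 4)
  expect_identical(sum(is.na(out$svl_mm)), 14L)
  expect_identical(out, inject_missing_svl(tab, 0.01, seed = 4))
  expect_identical(inject_missing_svl(tab, 0), tab)
  expect_error(inject_missing_svl(tab, 0.2), "fraction")
})
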