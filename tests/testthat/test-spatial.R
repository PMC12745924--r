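test_that("minimum convex polygon is the hull, oriented counter-clockwise", {
  tri <- data.frame(lon = c(0, 2, 1), lat = c(0, 0, 2))
  h <- mcp(tri)
  expect_identical(nrow(h), 3L)
  expect_equal(attr(h, "area"), 2)

  sq <- data.frame(lon = c(0, 1, 1, 0, 0.5), lat = c(0, 0, 1, 1, 0.5))
  h2 <- mcp(sq)
  expect_identical(nrow(h2), 4L)
  expect_equal(attr(h2, "area"), 1)  # shoelace oracle
  # counter-clockwise: signed shoelace area positive
  x <- h2[, 1]; y <- h2[, 2]
  signed <- 0.5 * sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
  expect_gt(signed, 0)

  # hull contains every input point
  for (i in seq_len(nrow(sq))) {
    expect_true(skinkipm:::point_in_polygon(sq$lon[i] * 0.999 + 1e-4,
                                            sq$lat[i] * 0.999 + 1e-4, h2))
  }
  expect_error(mcp(data.frame(lon = c(0, 1, 2), lat = c(0, 1, 2))), "collinear")
  expect_error(mcp(sq[1:2, ]), "3 points")
})

test_that("cropping preserves values and honours the buffer", {
  st <- simulate_climate_rasters(8, 6, 24, gradient = 0.2, seed = 3)
  tr <- st$transform
  # polygon covering pixel centres (2:5, 2:4) with zero buffer
  poly <- cbind(lon = tr["x0"] + tr["dx"] * c(1, 4, 4, 1),
                lat = tr["y0"] + tr["dy"] * c(3, 3, 1, 1))
  cr <- crop_with_buffer(st, poly, buffer = 0)
  expect_identical(dim(cr$tmax), c(3L, 4L, 24L))
  expect_equal(cr$tmax, st$tmax[2:4, 2:5, , drop = FALSE])

  # large buffer: output identical to input
  cr_all <- crop_with_buffer(st, poly, buffer = 20)
  expect_equal(cr_all$tmax, st$tmax)
  expect_equal(cr_all$transform, st$transform)

  far <- cbind(lon = c(100, 101, 101), lat = c(0, 0, 1))
  expect_error(crop_with_buffer(st, far, buffer = 0.1), "intersect")
})

test_that("VIF screening matches the correlation-matrix oracle and drops duplicates", {
  set.seed(11)
  x <- data.frame(a = rnorm(500), b = rnorm(500), c = rnorm(500))
  kept <- vif_screen(x)
  expect_setequal(kept, c("a", "b", "c"))
  expect_true(all(attr(kept, "vif") < 1.1))

  # oracle: VIF_j = diagonal of the inverse correlation matrix
  y <- x
  y$d <- 0.8 * x$a + 0.6 * x$b + rnorm(500, 0, 0.3)
  vifs <- attr(vif_screen(y, threshold = Inf), "vif")
  oracle <- diag(solve(cor(y)))
  expect_equal(unname(vifs[names(y)]), unname(oracle), tolerance = 1e-8)

  z <- x; z$dup <- x$a
  kept_z <- vif_screen(z)
  expect_identical(sum(c("a", "dup") %in% kept_z), 1L)
  expect_true("dup" %in% attr(kept_z, "dropped"))
})

test_that("uniform environments reproduce the single-site growth rate at every pixel", {
  ts <- truth_fit_set(n_env = 24)
  st <- simulate_climate_rasters(3, 3, 24, gradient = 0, seed = 1,
                                 noise_sd = 0, start_month = 1L)
  fld <- project_lambda(st, ts$fits, years = 1:2)
  # single-site reference from the same series
  ref_env <- pixel_series(st, 1, 1)
  ref_env$mean_svl <- unname(ts$fits$cjs$center["mean_svl"])
  lam_ref <- vapply(1:2, function(y) {
    kl <- kernel_series(ref_env[(y - 1) * 12 + 1:12, ], ts$fits)
    lambda_eigen(yearly_matrix(kl))$lambda
  }, numeric(1))
  for (y in 1:2) {
    expect_equal(unname(fld$yearly[, , y]), matrix(lam_ref[y], 3, 3),
                 tolerance = 1e-12)
  }
})

test_that("growth-rate maps are antitone along an imposed temperature gradient", {
  ts <- truth_fit_set(n_env = 36)
  st <- simulate_climate_rasters(6, 2, 36, gradient = 0.4, seed = 2,
                                 noise_sd = 0, trend = 0, start_month = 1L)
  fld <- project_lambda(st, ts$fits, years = 1:3)
  m <- fld$mean$all
  for (r in 1:2) expect_true(all(diff(m[r, ]) < 0))  # beta_tmax < 0
  # time-constant environment within the period: zero SD
  expect_lt(max(fld$sd$all), 1e-10)
})

test_that("period aggregation equals brute-force recomputation", {
  set.seed(12)
  cube <- array(runif(3 * 4 * 10, 0.8, 1.2), c(3, 4, 10))
  years <- 2005:2014
  agg <- period_aggregate(cube, years, list(p1 = c(2005, 2009), p2 = c(2010, 2014)))
  for (i in 1:3) for (j in 1:4) {
    expect_equal(agg$mean$p1[i, j], mean(cube[i, j, 1:5]))
    expect_equal(agg$sd$p2[i, j], sd(cube[i, j, 6:10]))
  }
  one <- period_aggregate(cube, years, list(y1 = c(2005, 2005)))
  expect_true(all(one$sd$y1 == 0))
  expect_equal(one$mean$y1, cube[, , 1])
  expect_error(period_aggregate(cube, years, list(bad = c(1990, 1991))),
               "no projected years")
})
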