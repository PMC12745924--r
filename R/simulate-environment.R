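#' Simulate a monthly environmental series
#'
#' Builds a monthly series of mean maximum temperature and precipitation with
#' a seasonal cycle (period 12), an optional linear warming trend, and
#' Gaussian noise. Precipitation follows a truncated seasonal model that
#' concentrates rain in an October--May wet season, as in seasonal Neotropical
#' savanna.
#'
#' @param n_months Number of months (>= 24; shorter series cannot support a
#'   seasonal decomposition).
#' @param seasonal_amp Amplitude of the temperature seasonal cycle (degrees C).
#' @param trend Linear temperature trend in degrees C per decade.
#' @param noise_sd SD of the Gaussian noise added to temperature (degrees C);
#'   precipitation noise is scaled from the same parameter.
#' @param baseline_tmax Mean maximum temperature (degrees C).
#' @param start_month Calendar month (1-12) of the first entry.
#' @param seed Integer seed.
#' @return A data frame of class `env_series` with columns `month_index`
#'   (1-based, consecutive), `month` (calendar month 1-12), `tmax` (degrees C)
#'   and `precip` (mm, non-negative).
#' @export
simulate_environment <- function(n_months, seasonal_amp = 3, trend = 0.2,
                                 noise_sd = 1, baseline_tmax = 27,
                                 start_month = 12L, seed = 1L) {
  if (n_months < 24) {
    stop("n_months must be at least 24: seasonal decomposition is undefined on shorter series")
  }
  set.seed(stage_seed(seed, "environment"))
  t <- seq_len(n_months)
  month <- ((start_month - 1L + t - 1L) %% 12L) + 1L
  # peak temperature at the end of the dry season (around September)
  tmax <- baseline_tmax +
    seasonal_amp * cos(2 * pi * (month - 9) / 12) +
    trend * (t - 1) / 120 +
    stats::rnorm(n_months, 0, noise_sd)
  # wet season October--May: seasonal cosine peaking in January, floored at 0
  precip_mean <- 120 + 140 * cos(2 * pi * (month - 1) / 12)
  precip <- pmax(0, precip_mean + stats::rnorm(n_months, 0, 25 * noise_sd))
  out <- data.frame(month_index = t, month = month, tmax = tmax, precip = precip)
  class(out) <- c("env_series", "data.frame")
  out
}

#' Simulate paired climate raster stacks with a known spatial gradient
#'
#' Every pixel carries the same base monthly environmental series (from
#' [simulate_environment()]); a deterministic west-to-east temperature
#' gradient is then added so that projected population-growth maps have a
#' known spatial ordering. Pixels are independent demographic units.
#'
#' @param nx,ny Grid dimensions (>= 2).
#' @param n_months Number of months.
#' @param gradient Temperature offset per pixel column (degrees C/cell),
#'   applied along the x axis.
#' @param origin Longitude/latitude of the grid's north-west pixel centre.
#' @param res Pixel size in degrees.
#' @param seed Integer seed.
#' @param ... Passed to [simulate_environment()].
#' @return An object of class `raster_stack`: a list with `tmax` and `precip`
#'   arrays of dimension `c(ny, nx, n_months)` (row 1 = northernmost row),
#'   `month_index`, `month`, an affine `transform` (x origin, pixel width,
#'   y origin, pixel height), and a `crs` tag (WGS84 lon/lat).
#' @export
simulate_climate_rasters <- function(nx, ny, n_months, gradient = 0.1,
                                     origin = c(-60, -10), res = 0.5,
                                     seed = 1L, ...) {
  stopifnot(nx >= 2, ny >= 2)
  base <- simulate_environment(n_months, seed = seed, ...)
  tmax <- array(NA_real_, c(ny, nx, n_months))
  precip <- array(NA_real_, c(ny, nx, n_months))
  for (m in seq_len(n_months)) {
    tmax[, , m] <- matrix(base$tmax[m] + gradient * (seq_len(nx) - 1),
                          nrow = ny, ncol = nx, byrow = TRUE)
    precip[, , m] <- base$precip[m]
  }
  structure(
    list(tmax = tmax, precip = precip,
         month_index = base$month_index, month = base$month,
         transform = c(x0 = origin[1], dx = res, y0 = origin[2], dy = -res),
         crs = "EPSG:4326"),
    class = "raster_stack")
}

#' @export
print.raster_stack <- function(x, ...) {
  d <- dim(x$tmax)
  cat(sprintf("raster_stack: %d x %d pixels, %d months, crs %s\n",
              d[2], d[1], d[3], x$crs))
  invisible(x)
}

#' Extract the environmental series of one pixel
#'
#' @param stack A `raster_stack`.
#' @param ix,iy Column and row indices (row 1 = northernmost).
#' @return An `env_series` data frame for that pixel.
#' @export
pixel_series <- function(stack, ix, iy) {
  out <- data.frame(month_index = stack$month_index, month = stack$month,
                    tmax = stack$tmax[iy, ix, ], precip = stack$precip[iy, ix, ])
  class(out) <- c("env_series", "data.frame")
  out
}

#' Write a raster stack as per-month TIFF layers with world files
#'
#' Each month of each variable is written as a single-band 32-bit float TIFF
#' accompanied by an ESRI world file carrying the affine georeference, plus a
#' `stack.json` sidecar with the month index and CRS tag.
#'
#' @param stack A `raster_stack`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_raster_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- stack$transform
  for (var in c("tmax", "precip")) {
    a <- stack[[var]]
    rng <- range(a)
    span <- if (diff(rng) > 0) diff(rng) else 1
    for (m in seq_len(dim(a)[3])) {
      f <- file.path(dir, sprintf("%s_%03d.tif", var, m))
      # tiff stores [0,1] floats; rescale and record the range in the sidecar
      tiff::writeTIFF((a[, , m] - rng[1]) / span, f, bits.per.sample = 32L,
                      reduce = TRUE)
      # world file: pixel width, rotations, pixel height, centre of upper-left pixel
      writeLines(format(c(tr["dx"], 0, 0, tr["dy"], tr["x0"], tr["y0"]),
                        digits = 17),
                 sub("\\.tif$", ".tfw", f))
    }
    jsonlite::write_json(list(min = rng[1], max = rng[2]),
                         file.path(dir, sprintf("%s_range.json", var)),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(
    list(month_index = stack$month_index, month = stack$month,
         transform = as.list(stack$transform), crs = stack$crs,
         ny = dim(stack$tmax)[1], nx = dim(stack$tmax)[2]),
    file.path(dir, "stack.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a raster stack written by [write_raster_stack()]
#'
#' @param dir Directory containing the TIFF layers and `stack.json`.
#' @return A `raster_stack`.
#' @export
read_raster_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "stack.json"), simplifyVector = TRUE)
  nm <- length(meta$month_index)
  out <- list(month_index = meta$month_index, month = meta$month,
              transform = unlist(meta$transform), crs = meta$crs)
  for (var in c("tmax", "precip")) {
    rng <- jsonlite::read_json(file.path(dir, sprintf("%s_range.json", var)),
                               simplifyVector = TRUE)
    a <- array(NA_real_, c(meta$ny, meta$nx, nm))
    for (m in seq_len(nm)) {
      z <- tiff::readTIFF(file.path(dir, sprintf("%s_%03d.tif", var, m)))
      a[, , m] <- rng$min + z * (rng$max - rng$min)
    }
    out[[var]] <- a
  }
  structure(out[c("tmax", "precip", "month_index", "month", "transform", "crs")],
            class = "raster_stack")
}
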