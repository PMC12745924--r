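#' Minimum convex polygon of occurrence records
#'
#' Convex hull of longitude/latitude points, the standard range proxy used to
#' delimit the region over which demographic projections are made.
#'
#' @param points Data frame or matrix with columns `lon`, `lat` (>= 3
#'   non-collinear points).
#' @return A matrix of hull vertices (`lon`, `lat`) in counter-clockwise
#'   order, with attribute `area` (shoelace area in square degrees).
#' @export
mcp <- function(points) {
  pts <- as.matrix(as.data.frame(points)[, c("lon", "lat")])
  if (nrow(pts) < 3) stop("need at least 3 points for a minimum convex polygon")
  idx <- grDevices::chull(pts)       # clockwise order
  hull <- pts[rev(idx), , drop = FALSE]  # counter-clockwise
  x <- hull[, 1]; y <- hull[, 2]
  area <- 0.5 * sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
  if (abs(area) < 1e-12) stop("points are collinear; polygon degenerate")
  attr(hull, "area") <- abs(area)
  hull
}

# point-in-polygon by ray casting (polygon as lon/lat vertex matrix)
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if (((poly[i, 2] > py) != (poly[j, 2] > py)) &&
        (px < (poly[j, 1] - poly[i, 1]) * (py - poly[i, 2]) /
           (poly[j, 2] - poly[i, 2]) + poly[i, 1])) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

#' Crop a raster stack to a buffered polygon bounding box
#'
#' Crops to the bounding box of the polygon expanded by `buffer` degrees on
#' every side (the reference region is the occurrence-record hull plus a
#' 2-degree margin), updating the geo-transform. Pixel values in the overlap
#' are preserved exactly.
#'
#' @param stack A `raster_stack`.
#' @param polygon Vertex matrix from [mcp()].
#' @param buffer Buffer width in degrees.
#' @return The cropped `raster_stack`.
#' @export
crop_with_buffer <- function(stack, polygon, buffer = 2) {
  tr <- stack$transform
  d <- dim(stack$tmax)
  cx <- tr["x0"] + tr["dx"] * (seq_len(d[2]) - 1)  # pixel-centre longitudes
  cy <- tr["y0"] + tr["dy"] * (seq_len(d[1]) - 1)  # latitudes, row 1 north
  xr <- range(polygon[, 1]) + c(-buffer, buffer)
  yr <- range(polygon[, 2]) + c(-buffer, buffer)
  keep_x <- which(cx >= xr[1] & cx <= xr[2])
  keep_y <- which(cy >= yr[1] & cy <= yr[2])
  if (!length(keep_x) || !length(keep_y)) {
    stop("polygon (plus buffer) does not intersect the raster")
  }
  out <- stack
  out$tmax <- stack$tmax[keep_y, keep_x, , drop = FALSE]
  out$precip <- stack$precip[keep_y, keep_x, , drop = FALSE]
  out$transform <- c(x0 = unname(cx[keep_x[1]]), dx = unname(tr["dx"]),
                     y0 = unname(cy[keep_y[1]]), dy = unname(tr["dy"]))
  out
}

#' Screen covariates by variance inflation factor
#'
#' Iteratively removes the covariate with the largest VIF
#' (`1 / (1 - R^2)` from regressing it on the remaining covariates) until all
#' VIFs are at or below the threshold. Perfectly collinear pairs are resolved
#' by dropping the later column.
#'
#' @param x Numeric matrix or data frame of candidate covariates (>= 2
#'   columns, more rows than columns).
#' @param threshold Maximum tolerated VIF (default 5).
#' @return Character vector of retained column names, with attribute `vif`
#'   (final VIFs) and `dropped`.
#' @export
vif_screen <- function(x, threshold = 5) {
  x <- as.data.frame(x)
  stopifnot(ncol(x) >= 2, nrow(x) > ncol(x))
  vif_of <- function(d) {
    vapply(seq_along(d), function(j) {
      y <- d[[j]]
      X <- cbind(1, as.matrix(d[-j]))
      res <- stats::lm.fit(X, y)$residuals
      r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  dropped <- character(0)
  while (ncol(x) > 1) {
    v <- vif_of(x)
    if (max(v) <= threshold) break
    worst <- which(v == max(v))
    worst <- worst[length(worst)]  # ties/collinearity: drop the later column
    dropped <- c(dropped, names(x)[worst])
    x <- x[-worst]
  }
  out <- names(x)
  attr(out, "vif") <- if (ncol(x) > 1) stats::setNames(vif_of(x), names(x))
                      else stats::setNames(1, names(x))
  attr(out, "dropped") <- dropped
  out
}

#' Project the population growth rate across a climate raster grid
#'
#' Builds 12 monthly IPM kernels per pixel per year from the pixel's climate
#' series, takes the yearly matrix's dominant eigenvalue, and aggregates
#' yearly growth rates to period means and SDs. Pixels are independent
#' demographic units (no dispersal). Pixels whose centres fall outside the
#' polygon (when given) are masked.
#'
#' @param stack A `raster_stack` whose months cover the requested years; the
#'   first layer is taken as January of `years[1]` unless the stack's
#'   `month` vector says otherwise.
#' @param fits Fit list as for [assemble_month()].
#' @param years Integer vector of consecutive years to project.
#' @param periods Named list of `c(first_year, last_year)` aggregation
#'   windows; defaults to a single window spanning `years`.
#' @param scenario Scenario tag stored on the result (e.g. "ssp245").
#' @param polygon Optional mask polygon from [mcp()].
#' @param mesh An [ipm_mesh()].
#' @return A `lambda_field`: list with `mean` and `sd` (lists of matrices,
#'   one per period, `NA` outside the mask), `yearly` (ny x nx x n_years
#'   array), `years`, `periods`, `scenario`, `transform`, `crs`.
#' @export
project_lambda <- function(stack, fits, years,
                           periods = list(all = range(years)),
                           scenario = "present", polygon = NULL,
                           mesh = ipm_mesh()) {
  d <- dim(stack$tmax)
  n_years <- length(years)
  if (d[3] < 12 * n_years) {
    missing_m <- 12 * n_years - d[3]
    stop(sprintf("stack is missing %d months for %d years of projection",
                 missing_m, n_years))
  }
  months <- stack$month[seq_len(12 * n_years)]
  # mean_svl is not observed per pixel: the CJS covariate is held at its
  # study-period mean (z-score 0)
  mean_svl_bar <- unname(fits$cjs$center["mean_svl"])

  tr <- stack$transform
  mask <- matrix(TRUE, d[1], d[2])
  if (!is.null(polygon)) {
    for (iy in seq_len(d[1])) for (ix in seq_len(d[2])) {
      px <- tr["x0"] + tr["dx"] * (ix - 1)
      py <- tr["y0"] + tr["dy"] * (iy - 1)
      mask[iy, ix] <- point_in_polygon(px, py, polygon)
    }
  }

  yearly <- array(NA_real_, c(d[1], d[2], n_years))
  for (iy in seq_len(d[1])) for (ix in seq_len(d[2])) {
    if (!mask[iy, ix]) next
    for (y in seq_len(n_years)) {
      sel <- (y - 1) * 12 + 1:12
      kl <- lapply(sel, function(m) {
        env <- data.frame(tmax = stack$tmax[iy, ix, m],
                          precip = stack$precip[iy, ix, m],
                          mean_svl = mean_svl_bar)
        assemble_month(mesh, months[m], env, fits)
      })
      yearly[iy, ix, y] <- lambda_eigen(yearly_matrix(kl))$lambda
    }
  }

  agg <- period_aggregate(yearly, years, periods)
  structure(list(mean = agg$mean, sd = agg$sd, yearly = yearly, years = years,
                 periods = periods, scenario = scenario,
                 transform = tr, crs = stack$crs),
            class = "lambda_field")
}

#' Aggregate yearly growth rates to period means and SDs
#'
#' @param yearly ny x nx x n_years array of yearly growth rates.
#' @param years Year labels of the third dimension.
#' @param periods Named list of `c(first_year, last_year)` windows.
#' @return List with `mean` and `sd`: named lists of ny x nx matrices.
#' @export
period_aggregate <- function(yearly, years, periods) {
  means <- list(); sds <- list()
  for (nm in names(periods)) {
    pr <- periods[[nm]]
    sel <- which(years >= pr[1] & years <= pr[2])
    if (!length(sel)) stop(sprintf("period '%s' contains no projected years", nm))
    means[[nm]] <- apply(yearly[, , sel, drop = FALSE], c(1, 2), mean)
    sds[[nm]] <- if (length(sel) == 1) {
      matrix(0, dim(yearly)[1], dim(yearly)[2]) +
        ifelse(is.na(yearly[, , sel]), NA_real_, 0)
    } else {
      apply(yearly[, , sel, drop = FALSE], c(1, 2), stats::sd)
    }
  }
  list(mean = means, sd = sds)
}
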