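#' Impute missing snout-vent lengths by iterative random-forest regression
#'
#' Missing (or outlier-blanked) SVL values are filled by missForest-style
#' iterative nonparametric imputation: missing entries start at the column
#' mean, a random forest of SVL on body mass, sex, tail length and tail
#' condition is fitted to the currently complete table, missing entries are
#' replaced by its predictions, and the cycle repeats until the imputed
#' values change by less than `tol` (mm) or `max_iter` is reached. Observed
#' values are never altered.
#'
#' @param table Capture table with columns `svl_mm`, `mass_g`, `sex`,
#'   `tail_mm`, `tail_intact`.
#' @param max_iter Maximum refinement iterations.
#' @param tol Convergence tolerance on the mean absolute change of imputed
#'   values (mm).
#' @param seed Integer seed (random forests are stochastic).
#' @return The table with no missing SVL, plus attribute `imputed_rows`
#'   (integer row indices that were filled).
#' @export
impute_svl <- function(table, max_iter = 10L, tol = 0.1, seed = 1L) {
  miss <- which(is.na(table$svl_mm))
  if (length(miss) == 0) return(table)
  if (length(miss) == nrow(table)) stop("all SVL values missing; imputation impossible")
  if (length(miss) / nrow(table) >= 0.1) {
    stop("more than 10% of SVL missing; refusing to impute")
  }
  set.seed(stage_seed(seed, "impute"))
  dat <- data.frame(svl = table$svl_mm,
                    mass = table$mass_g,
                    sex = factor(table$sex),
                    tail = table$tail_mm,
                    tail_intact = factor(table$tail_intact))
  dat$svl[miss] <- mean(dat$svl, na.rm = TRUE)
  prev <- dat$svl[miss]
  for (it in seq_len(max_iter)) {
    rf <- randomForest::randomForest(
      svl ~ mass + sex + tail + tail_intact,
      data = dat[-miss, , drop = FALSE], ntree = 200)
    dat$svl[miss] <- stats::predict(rf, dat[miss, , drop = FALSE])
    if (mean(abs(dat$svl[miss] - prev)) < tol) break
    prev <- dat$svl[miss]
  }
  table$svl_mm[miss] <- dat$svl[miss]
  attr(table, "imputed_rows") <- miss
  table
}

#' Flag outlier SVL records before imputation
#'
#' Operationalises "outlier" as an SVL further than `k` median absolute
#' deviations from the sex-specific median; flagged values are blanked so
#' that [impute_svl()] replaces them.
#'
#' @param table Capture table.
#' @param k MAD multiplier (default 4).
#' @return The table with outlier SVL set to `NA`; attribute `outlier_rows`
#'   lists the blanked rows.
#' @export
flag_svl_outliers <- function(table, k = 4) {
  out <- integer(0)
  for (s in unique(table$sex)) {
    idx <- which(table$sex == s & !is.na(table$svl_mm))
    med <- stats::median(table$svl_mm[idx])
    mad <- stats::mad(table$svl_mm[idx])
    if (mad == 0) next
    out <- c(out, idx[abs(table$svl_mm[idx] - med) > k * mad])
  }
  table$svl_mm[out] <- NA_real_
  attr(table, "outlier_rows") <- sort(out)
  table
}

#' Build consecutive-capture growth intervals
#'
#' Pairs each individual's consecutive captures into (initial SVL, final SVL,
#' elapsed months) triples for Fabens growth fitting. Individuals of unknown
#' sex are excluded. Intervals whose initial SVL reaches or exceeds the
#' sex-specific asymptotic-SVL starting estimate (the largest observed SVL of
#' that sex) are flagged: the growth model assumes SVL never exceeds the
#' asymptote, so such records are removed before fitting.
#'
#' @param table Cleaned capture table (no missing SVL).
#' @return A data frame of class `recapture_intervals` with columns `id`,
#'   `sex`, `L0`, `L1`, `dt` and logical `flag_linf`; attribute
#'   `n_excluded_unknown_sex` counts the dropped unknown-sex captures.
#' @export
build_recapture_intervals <- function(table) {
  known <- table[table$sex %in% c("F", "M"), ]
  n_unknown <- nrow(table) - nrow(known)
  known <- known[order(known$id, known$session), ]
  linf0 <- tapply(known$svl_mm, known$sex, max)
  res <- lapply(split(known, known$id), function(d) {
    if (nrow(d) < 2) return(NULL)
    i <- seq_len(nrow(d) - 1)
    data.frame(id = d$id[i], sex = d$sex[i],
               L0 = d$svl_mm[i], L1 = d$svl_mm[i + 1],
               dt = d$session[i + 1] - d$session[i])
  })
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(id = character(), sex = character(), L0 = numeric(),
                      L1 = numeric(), dt = numeric())
  }
  rownames(out) <- NULL
  out$flag_linf <- out$L0 >= linf0[out$sex]
  attr(out, "n_excluded_unknown_sex") <- n_unknown
  class(out) <- c("recapture_intervals", "data.frame")
  out
}

#' Attach monthly mean SVL to an environmental series
#'
#' Computes the mean SVL of all captures in each month, used as a
#' population-structure covariate in the Cormack-Jolly-Seber model. Months
#' with no captures are filled with the overall mean SVL and flagged, so the
#' survival stage can drop or keep them explicitly.
#'
#' @param table Capture table.
#' @param env An `env_series` spanning all sessions.
#' @return `env` with new columns `mean_svl` and logical `svl_filled`.
#' @export
monthly_covariates <- function(table, env) {
  stopifnot(all(table$session %in% env$month_index))
  m <- tapply(table$svl_mm, table$session, mean)
  env$mean_svl <- as.numeric(m[as.character(env$month_index)])
  env$svl_filled <- is.na(env$mean_svl)
  env$mean_svl[env$svl_filled] <- mean(table$svl_mm, na.rm = TRUE)
  env
}

#' Convert a capture table to a detection-history matrix
#'
#' @param table Capture table.
#' @param n_occasions Number of monthly occasions (columns).
#' @return A 0/1 matrix with one row per individual (rownames = ids), plus
#'   attribute `sex` (one entry per row).
#' @export
capture_histories <- function(table, n_occasions = max(table$session)) {
  ids <- sort(unique(table$id))
  h <- matrix(0L, length(ids), n_occasions, dimnames = list(ids, NULL))
  h[cbind(match(table$id, ids), table$session)] <- 1L
  sex <- table$sex[match(ids, table$id)]
  attr(h, "sex") <- sex
  h
}
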