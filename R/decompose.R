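#' Classical additive seasonal decomposition of a monthly series
#'
#' Splits a monthly demographic series (survival, population growth rate)
#' into trend (centred 12-month moving average), seasonal (month-wise mean of
#' the detrended series, re-centred to zero mean) and residual components,
#' exactly as in classical additive decomposition. The input equals
#' trend + seasonal + residual wherever the trend is defined (the first and
#' last six months carry `NA` trend).
#'
#' @param series Numeric vector (length >= 2 * `period`).
#' @param period Seasonal period (12 for monthly data).
#' @return A `decomposition_result`: data frame with `value`, `trend`,
#'   `seasonal`, `residual`, plus attribute `period`.
#' @export
decompose_series <- function(series, period = 12L) {
  if (length(series) < 2 * period) {
    stop("series must span at least two full periods")
  }
  dec <- stats::decompose(stats::ts(series, frequency = period), type = "additive")
  out <- data.frame(value = series,
                    trend = as.numeric(dec$trend),
                    seasonal = as.numeric(dec$seasonal),
                    residual = as.numeric(dec$random))
  attr(out, "period") <- period
  class(out) <- c("decomposition_result", "data.frame")
  out
}

#' Variance shares of decomposition components
#'
#' The fraction of temporal variation attributed to each component:
#' `share_c = var(component_c) / sum_c var(component_c)`, computed over the
#' months where all three components are defined. The three shares are
#' non-negative and sum to one.
#'
#' @param result A `decomposition_result`.
#' @return Named numeric vector `c(seasonal, trend, residual)`.
#' @export
variance_shares <- function(result) {
  ok <- stats::complete.cases(result[, c("trend", "seasonal", "residual")])
  v <- c(seasonal = stats::var(result$seasonal[ok]),
         trend = stats::var(result$trend[ok]),
         residual = stats::var(result$residual[ok]))
  total <- sum(v)
  if (total == 0) stop("series has zero variance; shares undefined")
  v / total
}
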