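#' Geometric mean
#'
#' Summary statistic used to aggregate per-subject pharmacokinetic parameters
#' (Cmax, AUC) across a study arm before computing prediction errors.
#'
#' @param x numeric vector of strictly positive values.
#' @param na.rm drop missing values before averaging.
#' @return `exp(mean(log(x)))`.
#' @examples
#' geometric_mean(c(4, 9)) # 6
#' @export
geometric_mean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (length(x) == 0L) stop("no values to average")
  if (any(is.na(x))) stop("missing values in 'x'; use na.rm = TRUE to drop them")
  if (any(x <= 0)) stop("geometric mean requires strictly positive values")
  exp(mean(log(x)))
}

#' Harmonic mean
#'
#' Conventional summary for terminal half-life across subjects: n / sum(1/x).
#' The pseudo-standard deviation is the jackknife SD of the harmonic mean.
#'
#' @param x numeric vector of strictly positive values.
#' @return named numeric vector with elements `mean` and `pseudo_sd`.
#' @export
harmonic_mean <- function(x) {
  if (any(is.na(x)) || any(x <= 0)) stop("harmonic mean requires strictly positive values")
  n <- length(x)
  hm <- n / sum(1 / x)
  psd <- if (n > 1) {
    jack <- vapply(seq_len(n), function(i) (n - 1) / sum(1 / x[-i]), numeric(1))
    sqrt((n - 1) / n * sum((jack - mean(jack))^2)) * sqrt(n)
  } else NA_real_
  c(mean = hm, pseudo_sd = psd)
}

# Linear trapezoidal quadrature on (possibly irregular) time grid.
trapz_auc <- function(t, y) {
  if (length(t) < 2L) return(0)
  sum(diff(t) * (y[-length(y)] + y[-1]) / 2)
}

# AIC on the least-squares deviance scale: n*log(sse/n) + 2k.  The sse is
# floored at (reltol * data scale)^2 per point so that model selection on
# noiseless data is decided by parsimony (2k) rather than by which candidate
# happens to drive the residual closer to machine zero.
aic_ls <- function(sse, n, k, scale = 1, reltol = 1e-8) {
  floor_sse <- n * (reltol * max(scale, .Machine$double.xmin))^2
  n * log(max(sse, floor_sse) / n) + 2 * k
}

# shared input checks
check_times <- function(t, what = "times", require_zero = FALSE) {
  if (any(is.na(t))) stop(what, " contain missing values")
  if (any(t < 0)) stop(what, " must be nonnegative")
  d <- diff(t)
  if (any(d <= 0)) {
    i <- which(d <= 0)[1] + 1L
    stop(what, " must be strictly increasing (violated at position ", i, ")")
  }
  if (require_zero && abs(t[1]) > 1e-9) stop(what, " must start at 0")
  invisible(t)
}
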