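#' Noncompartmental analysis of a concentration-time profile
#'
#' Computes the standard single-dose NCA parameters: Cmax and Tmax by direct
#' inspection (earliest time on ties), AUC to the last quantifiable
#' concentration by the linear trapezoidal method, the terminal elimination
#' rate constant (lambda_z, often written beta) by log-linear regression over
#' an automatically selected terminal window, the terminal half-life
#' ln(2)/lambda_z, and AUC extrapolated to infinity as
#' AUClast + Clast/lambda_z (observed Clast).
#'
#' BLQ handling: samples below the LLOQ before the first quantifiable
#' concentration are set to 0 for the trapezoid; embedded and trailing BLQ
#' samples are excluded throughout.  The terminal window is chosen among all
#' windows of at least `min_points` consecutive points, strictly after Tmax,
#' ending at the last quantifiable point: the window with the best adjusted
#' R-squared wins, with ties (within `r2_tol`) broken toward more points.
#'
#' @param profile a [pk_profile], or a plain list with elements `times` and
#'   `concentrations`.
#' @param min_points minimum number of points in the lambda_z regression.
#' @param r2_tol adjusted-R-squared tolerance within which a longer window is
#'   preferred.
#' @return an object of class `nca_result`: `cmax`, `tmax`, `auc_last`,
#'   `auc_inf`, `lambda_z`, `t_half`, `n_lambda_points`, `r2_adj`,
#'   `extrap_pct` (percent of auc_inf due to extrapolation).  When no valid
#'   terminal slope exists, `lambda_z`, `t_half` and `auc_inf` are `NA`.
#' @export
compute_nca <- function(profile, min_points = 3L, r2_tol = 1e-4) {
  if (inherits(profile, "pk_profile")) {
    q <- quantifiable(profile, keep_leading_zero = TRUE)
  } else {
    q <- list(times = profile$times, conc = profile$concentrations)
  }
  t <- q$times; y <- q$conc
  # Cmax/Tmax and AUClast need only a profile; the terminal slope (and with
  # it AUCinf, t1/2) additionally needs >= min_points usable points
  if (sum(y > 0) < 1L || length(y) < 2L)
    stop("NCA needs a quantifiable concentration profile")
  cmax <- max(y)
  tmax <- t[which(y == cmax)[1]]
  auc_last <- trapz_auc(t, y)
  # lambda_z: candidate windows are suffixes of the positive-concentration
  # points strictly after tmax
  cand <- which(t > tmax & y > 0)
  lambda_z <- t_half <- auc_inf <- r2_adj <- extrap_pct <- NA_real_
  n_pts <- NA_integer_
  if (length(cand) >= min_points) {
    fits <- lapply(seq_len(length(cand) - min_points + 1L), function(i) {
      idx <- cand[i:length(cand)]
      tt <- t[idx]; ly <- log(y[idx])
      n <- length(idx)
      sl <- stats::cov(tt, ly) / stats::var(tt)
      if (!is.finite(sl) || sl >= 0) return(NULL)
      r2 <- stats::cor(tt, ly)^2
      list(lambda = -sl, r2a = 1 - (1 - r2) * (n - 1) / (n - 2), n = n)
    })
    fits <- Filter(Negate(is.null), fits)
    if (length(fits)) {
      r2a <- vapply(fits, `[[`, numeric(1), "r2a")
      ok <- which(r2a >= max(r2a) - r2_tol)
      pick <- fits[[ok[which.max(vapply(fits[ok], `[[`, numeric(1), "n"))]]]
      lambda_z <- pick$lambda
      t_half <- log(2) / lambda_z
      r2_adj <- pick$r2a
      n_pts <- pick$n
      c_last <- y[length(y)]
      auc_inf <- auc_last + c_last / lambda_z
      extrap_pct <- 100 * (auc_inf - auc_last) / auc_inf
      if (extrap_pct > 20)
        warning(sprintf("AUC extrapolation is %.1f%% of AUCinf", extrap_pct))
    }
  }
  structure(
    list(cmax = cmax, tmax = tmax, auc_last = auc_last, auc_inf = auc_inf,
         lambda_z = lambda_z, t_half = t_half, n_lambda_points = n_pts,
         r2_adj = r2_adj, extrap_pct = extrap_pct),
    class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat("NCA result:\n")
  cat(sprintf("  Cmax  %.4g ng/mL at Tmax %.3g h\n", x$cmax, x$tmax))
  cat(sprintf("  AUClast %.5g, AUCinf %.5g ng*h/mL (%.1f%% extrapolated)\n",
              x$auc_last, x$auc_inf, x$extrap_pct))
  cat(sprintf("  lambda_z %.4g 1/h (t1/2 %.3g h; %d points, adj R2 %.4f)\n",
              x$lambda_z, x$t_half, x$n_lambda_points, x$r2_adj))
  invisible(x)
}

#' Per-subject NCA table for a study dataset
#'
#' @param dataset a [study_dataset].
#' @param regimens regimens to include (default all).
#' @param ... passed to [compute_nca].
#' @return data frame with columns subject, regimen, parameter, value in long
#'   format, ready for CSV export.
#' @export
nca_table <- function(dataset, regimens = NULL, ...) {
  profiles <- dataset_profiles(dataset, regimen = regimens)
  rows <- lapply(profiles, function(p) {
    r <- compute_nca(p, ...)
    data.frame(subject = p$subject_id, regimen = p$regimen,
               parameter = c("cmax", "tmax", "auc_last", "auc_inf", "t_half"),
               value = c(r$cmax, r$tmax, r$auc_last, r$auc_inf, r$t_half))
  })
  do.call(rbind, rows)
}
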