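#' Control parameters for IVIVC fitting
#'
#' @param dissolution_model dissolution family: `"auto"` (AIC selection),
#'   `"weibull"`, or `"hill"`.
#' @param free_finf estimate the dissolution plateau instead of fixing it
#'   to 1.
#' @param max_uir_exp maximum number of UIR disposition exponentials (1-3).
#' @param grid optional deconvolution grid in hours; default: each ER
#'   profile's own observation times.
#' @param basis deconvolution input-rate basis, see [deconvolve].
#' @param smooth second-difference smoothing weight for deconvolution
#'   (default 0, off).
#' @param time_limit span (h) of the stage-2 correlation fit; `NULL` limits
#'   it to the span of the in vitro dissolution data (beyond which both the
#'   dissolution curve and the deconvolved tail are extrapolation);
#'   `Inf` uses the full profile.
#' @param refine apply the operator-consistent refinement
#'   ([refine_emax_timescale]) after the Emax time-scale fit.
#' @param lambda_z_min_points minimum points in the terminal-slope
#'   regression.
#' @param starts multi-start matrix for the Emax time-scale fit.
#' @param per_subject fit the stage-2 correlation on per-subject absorption
#'   profiles instead of the per-formulation mean profiles.
#' @param verbose emit stage-level progress messages.
#' @return list of class `ivivc_control`.
#' @export
ivivc_control <- function(dissolution_model = c("auto", "weibull", "hill"),
                          free_finf = FALSE,
                          max_uir_exp = 3L,
                          grid = NULL,
                          basis = c("linear", "step"),
                          smooth = 0,
                          time_limit = NULL,
                          refine = TRUE,
                          lambda_z_min_points = 3L,
                          starts = timescale_starts(),
                          per_subject = FALSE,
                          verbose = FALSE) {
  dissolution_model <- match.arg(dissolution_model)
  basis <- match.arg(basis)
  stopifnot(max_uir_exp >= 1L, max_uir_exp <= 3L, smooth >= 0,
            lambda_z_min_points >= 3L)
  if (!is.null(grid)) check_times(grid, "deconvolution grid")
  structure(list(dissolution_model = dissolution_model, free_finf = free_finf,
                 max_uir_exp = as.integer(max_uir_exp), grid = grid,
                 basis = basis, smooth = smooth, time_limit = time_limit,
                 refine = refine,
                 lambda_z_min_points = as.integer(lambda_z_min_points),
                 starts = starts, per_subject = per_subject,
                 verbose = verbose),
            class = "ivivc_control")
}

#' Develop and validate a level A IVIVC
#'
#' Runs the complete two-stage IVIVC workflow on a crossover study dataset:
#' \enumerate{
#'   \item fit parametric dissolution curves per formulation (AIC-selected
#'     Weibull/Hill);
#'   \item fit each subject's unit impulse response from the IR reference
#'     arm (polyexponential with absorption stripping);
#'   \item numerically deconvolve every ER plasma profile against the
#'     subject's UIR to obtain cumulative fraction absorbed, and average
#'     per formulation;
#'   \item fit the stage-2 correlation on the internal formulations —
#'     nonlinear Emax time scaling by default, or a conventional linear
#'     model;
#'   \item predict individual plasma profiles by convolution and evaluate
#'     the FDA/EMA prediction-error criteria internally and externally.
#' }
#'
#' @param data a [study_dataset] (e.g. from [read_concentrations] or
#'   [simulate_study]).
#' @param internal,external formulation role assignment; default: the
#'   dataset's.
#' @param correlation `"emax"` (nonlinear time scaling) or `"linear"`.
#' @param linear_variant variant passed to [fit_linear_ivivc] when
#'   `correlation = "linear"`.
#' @param control an [ivivc_control] list.
#' @return an object of class `ivivc` with components `dissolution_fits`,
#'   `uirs`, `fa` (per-subject absorption profiles), `fa_mean`
#'   (per-formulation mean profiles), `model` (the stage-2 fit),
#'   `validation` (an `ivivc_validation`), and `call`.
#' @seealso [ivivc_loo] for leave-one-out cross-validation,
#'   [validate_ivivc], [fit_emax_timescale].
#' @examples
#' \donttest{
#' ds <- simulate_study(study_spec(n_subjects = 6), seed = 7)
#' fit <- ivivc(ds)
#' print(fit)
#' coef(fit)
#' }
#' @export
ivivc <- function(data, internal = data$internal_formulations,
                  external = data$external_formulations,
                  correlation = c("emax", "linear"),
                  linear_variant = "scale+shift",
                  control = ivivc_control()) {
  stopifnot(inherits(data, "study_dataset"))
  correlation <- match.arg(correlation)
  say <- if (isTRUE(control$verbose)) message else function(...) invisible()
  forms <- sort(unique(c(internal, external)))

  say("stage 1: dissolution model fitting (", length(forms), " formulations)")
  dissolution_fits <- lapply(forms, function(f)
    fit_dissolution(dataset_dissolution(data, f),
                    model = control$dissolution_model,
                    free_finf = control$free_finf))
  names(dissolution_fits) <- forms

  say("stage 2: unit impulse response fitting")
  ir <- dataset_profiles(data, regimen = data$reference_regimen)
  uirs <- lapply(ir, fit_uir, max_exp = control$max_uir_exp)
  names(uirs) <- vapply(uirs, `[[`, character(1), "subject_id")

  say("stage 3: numerical deconvolution")
  fa <- list()
  for (f in forms) {
    for (p in dataset_profiles(data, regimen = f)) {
      u <- uirs[[p$subject_id]]
      if (is.null(u)) stop("no UIR for subject ", p$subject_id)
      fa[[length(fa) + 1L]] <- deconvolve(p, u, grid = control$grid,
                                          basis = control$basis,
                                          smooth = control$smooth)
    }
  }
  fa_mean <- lapply(forms, function(f)
    mean_absorption_profile(Filter(function(a) a$formulation_id == f, fa)))
  names(fa_mean) <- forms

  say("stage 4: ", correlation, " correlation fit on ",
      paste(internal, collapse = ", "))
  t_limit <- control$time_limit
  if (is.null(t_limit))
    t_limit <- max(vapply(data$dissolution, function(d) max(d$times), 1),
                   na.rm = TRUE)
  fa_fit <- if (isTRUE(control$per_subject)) {
    keep <- Filter(function(a) a$formulation_id %in% internal, fa)
    stats::setNames(keep, vapply(keep, `[[`, character(1), "formulation_id"))
  } else fa_mean[internal]
  fa_fit <- lapply(fa_fit, truncate_absorption, t_limit = t_limit)
  model <- if (correlation == "emax")
    fit_emax_timescale(fa_fit, dissolution_fits, starts = control$starts)
  else
    fit_linear_ivivc(fa_fit, dissolution_fits, variant = linear_variant)
  if (correlation == "emax" && isTRUE(control$refine)) {
    say("stage 4b: operator-consistent refinement")
    fa_int <- Filter(function(a) a$formulation_id %in% internal, fa)
    model <- refine_emax_timescale(model, fa_int, dissolution_fits, uirs,
                                   time_limit = t_limit)
  }

  say("stage 5: convolution prediction and validation")
  validation <- validate_ivivc(data, model, dissolution_fits, uirs,
                               internal = internal, external = external)
  structure(
    list(dissolution_fits = dissolution_fits, uirs = uirs,
         fa = fa, fa_mean = fa_mean, model = model,
         correlation = correlation, validation = validation,
         internal = internal, external = external,
         data = data, control = control, call = match.call()),
    class = "ivivc")
}

#' @export
print.ivivc <- function(x, ...) {
  cat("Level A IVIVC (", x$correlation, " correlation)\n", sep = "")
  cat("  formulations: internal ", paste(x$internal, collapse = ", "),
      if (length(x$external)) paste0("; external ", paste(x$external, collapse = ", ")),
      "\n", sep = "")
  print(x$model)
  crit <- x$validation$criteria
  cat("Validation: internal ", if (isTRUE(crit$internal_pass)) "PASS" else "FAIL",
      if (!is.na(crit$external_pass))
        paste0("; external ", if (isTRUE(crit$external_pass)) "PASS" else "FAIL"),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.ivivc <- function(object, ...) {
  structure(list(fit = object), class = "summary.ivivc")
}

#' @export
print.summary.ivivc <- function(x, ...) {
  fit <- x$fit
  cat("Level A IVIVC summary\n=====================\n\nDissolution fits:\n")
  for (f in names(fit$dissolution_fits)) {
    d <- fit$dissolution_fits[[f]]
    cat(sprintf("  %s: %s, MDT %.3g h, b %.3g (AIC %.1f)\n",
                f, d$model, d$mdt, d$b, d$aic))
  }
  nexp <- vapply(fit$uirs, `[[`, integer(1), "n_exp")
  r2 <- vapply(fit$uirs, `[[`, numeric(1), "r_squared")
  cat(sprintf("\nUIR fits: %d subjects; exponentials chosen: %s; min R2 %.3f\n",
              length(fit$uirs),
              paste(names(table(nexp)), table(nexp), sep = "x", collapse = ", "),
              min(r2)))
  cat("\nStage-2 correlation:\n")
  print(fit$model)
  cat("\n")
  print(fit$validation)
  invisible(x)
}

#' @export
coef.ivivc <- function(object, ...) coef(object$model)

#' @export
residuals.ivivc <- function(object, ...) residuals(object$model)

#' Predict from a fitted IVIVC
#'
#' Given a new formulation's dissolution behaviour, predicts either its in
#' vivo cumulative fraction absorbed (`type = "fa"`) or, using the study's
#' individual unit impulse responses, the geometric-mean plasma
#' concentration profile (`type = "concentration"`).
#'
#' @param object a fitted `ivivc`.
#' @param dissolution a [dissolution_profile] (it is fitted on the fly) or
#'   an existing `dissolution_fit`; default: the first internal
#'   formulation's fit.
#' @param times output times in hours.
#' @param type `"fa"` or `"concentration"`.
#' @param dose_mg ER dose for concentration predictions.
#' @param ... unused.
#' @return for `"fa"`, an `absorption_profile`; for `"concentration"`, a
#'   data frame (time_h, conc_ng_ml) of the geometric mean across subjects.
#' @export
predict.ivivc <- function(object, dissolution = NULL,
                          times = NULL, type = c("fa", "concentration"),
                          dose_mg = NULL, ...) {
  type <- match.arg(type)
  dfit <- if (is.null(dissolution)) {
    object$dissolution_fits[[object$internal[1]]]
  } else if (inherits(dissolution, "dissolution_profile")) {
    fit_dissolution(dissolution, model = object$control$dissolution_model)
  } else dissolution
  if (is.null(times)) {
    ts <- object$data$profiles[[1]]$times
    times <- c(0, ts[ts > 0])
  }
  fa <- predict_fa(object$model, dfit, sort(unique(c(0, times))))
  if (type == "fa") return(fa)
  if (is.null(dose_mg)) {
    er <- dataset_profiles(object$data,
                           regimen = c(object$internal, object$external))
    dose_mg <- if (length(er)) er[[1]]$dose_mg else 1
  }
  cmat <- vapply(object$uirs, function(u)
    convolve_predict(fa, u, dose_mg, times)$concentrations,
    numeric(length(times)))
  gm <- apply(cmat, 1, function(v) if (all(v > 0)) geometric_mean(v) else mean(v))
  data.frame(time_h = times, conc_ng_ml = gm)
}

#' Diagnostic plots for a fitted IVIVC
#'
#' Four panels: fitted dissolution curves with data; deconvolved mean
#' absorption profiles; observed fraction absorbed against the mapped
#' dissolution curve (the stage-2 fit); and observed versus predicted
#' summary parameters on the identity line.
#'
#' @param x a fitted `ivivc`.
#' @param which subset of panels 1:4.
#' @param ... unused.
#' @export
plot.ivivc <- function(x, which = 1:4, ...) {
  op <- graphics::par(mfrow = c(ceiling(length(which) / 2),
                                min(2, length(which))),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  forms <- names(x$dissolution_fits)
  cols <- stats::setNames(grDevices::hcl.colors(max(3, length(forms)), "Dark 3")[
    seq_along(forms)], forms)
  if (1 %in% which) {
    tg <- seq(0, max(vapply(x$data$dissolution, function(d) max(d$times), 1)),
              length.out = 200)
    graphics::plot(NA, xlim = range(tg), ylim = c(0, 1.05),
                   xlab = "time (h)", ylab = "fraction dissolved",
                   main = "Dissolution fits")
    for (f in forms) {
      graphics::lines(tg, predict(x$dissolution_fits[[f]], tg), col = cols[f])
      for (d in dataset_dissolution(x$data, f))
        graphics::points(d$times, d$fraction_dissolved, col = cols[f], pch = 1)
    }
    graphics::legend("bottomright", legend = forms, col = cols, lty = 1, bty = "n")
  }
  if (2 %in% which) {
    graphics::plot(NA, xlim = c(0, max(x$fa_mean[[1]]$times)), ylim = c(0, 1.1),
                   xlab = "time (h)", ylab = "fraction absorbed",
                   main = "Mean absorption (deconvolved)")
    for (f in forms)
      graphics::lines(x$fa_mean[[f]]$times, x$fa_mean[[f]]$fa, col = cols[f],
                      type = "b", pch = 16, cex = 0.6)
  }
  if (3 %in% which && inherits(x$model, "timescale_fit")) {
    d <- x$model$data
    graphics::plot(d$fa, x$model$fitted, col = cols[d$formulation],
                   xlab = "observed Fa", ylab = "F_diss at mapped time",
                   main = "Stage-2 Emax time-scale fit")
    graphics::abline(0, 1, lty = 2)
  }
  if (4 %in% which) {
    rec <- x$validation$records
    graphics::plot(rec$observed, rec$predicted, log = "xy",
                   col = cols[rec$formulation],
                   pch = ifelse(rec$role == "internal", 16, 1),
                   xlab = "observed (geometric mean)",
                   ylab = "predicted (geometric mean)",
                   main = "Observed vs predicted Cmax/AUC")
    graphics::abline(0, 1, lty = 2)
  }
  invisible(x)
}

#' Leave-one-out cross-validation of a level A IVIVC
#'
#' Convenience wrapper: fits the shared stage-1 artifacts (dissolution,
#' UIR, deconvolution) once, then delegates to [leave_one_out], holding out
#' each ER formulation in turn.
#'
#' @param data a [study_dataset] with at least 3 ER formulations.
#' @param control an [ivivc_control].
#' @return an `ivivc_loo` object.
#' @export
ivivc_loo <- function(data, control = ivivc_control()) {
  forms <- sort(unique(c(data$internal_formulations,
                         data$external_formulations)))
  fit <- ivivc(data, internal = forms, external = character(0),
               control = control)
  leave_one_out(data, fit$dissolution_fits, fit$uirs, fit$fa,
                starts = control$starts, time_limit = control$time_limit,
                refine = control$refine)
}
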