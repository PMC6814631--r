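#' In vitro dissolution profile
#'
#' Container for one formulation's cumulative fraction dissolved versus time.
#' Times are in hours and must start at 0; the dissolved fraction is
#' dimensionless (assay scatter may push individual points slightly above 1).
#'
#' @param formulation_id formulation label (e.g. `"A"`).
#' @param times sampling times in hours, strictly increasing, first equal 0.
#' @param fraction_dissolved cumulative fraction dissolved at each time,
#'   in `[0, 1.05]`; the value at t = 0 must be 0 within 0.01.
#' @param hpmc_pct nominal release-controlling polymer load in percent
#'   (metadata only).
#' @param replicate_id optional replicate label (vessel, run).
#' @return an object of class `dissolution_profile`.
#' @export
dissolution_profile <- function(formulation_id, times, fraction_dissolved,
                                hpmc_pct = NA_real_, replicate_id = NULL) {
  times <- as.numeric(times)
  fraction_dissolved <- as.numeric(fraction_dissolved)
  if (length(times) != length(fraction_dissolved))
    stop("times and fraction_dissolved differ in length")
  check_times(times, "dissolution times", require_zero = TRUE)
  if (any(is.na(fraction_dissolved))) stop("fraction_dissolved contains missing values")
  if (any(fraction_dissolved < -1e-9) || any(fraction_dissolved > 1.05))
    stop("fraction_dissolved must lie in [0, 1.05]; got range [",
         signif(min(fraction_dissolved), 3), ", ", signif(max(fraction_dissolved), 3), "]")
  if (abs(fraction_dissolved[1]) > 0.01)
    stop("fraction dissolved at t = 0 must be 0 (within 0.01)")
  structure(
    list(formulation_id = as.character(formulation_id),
         hpmc_pct = as.numeric(hpmc_pct),
         times = times,
         fraction_dissolved = fraction_dissolved,
         replicate_id = if (is.null(replicate_id)) NA_character_ else as.character(replicate_id)),
    class = "dissolution_profile")
}

#' @export
print.dissolution_profile <- function(x, ...) {
  cat("Dissolution profile: formulation", x$formulation_id)
  if (!is.na(x$hpmc_pct)) cat(" (", x$hpmc_pct, "% HPMC)", sep = "")
  if (!is.na(x$replicate_id)) cat(", replicate", x$replicate_id)
  cat("\n ", length(x$times), "timepoints over", max(x$times), "h; final fraction",
      signif(x$fraction_dissolved[length(x$times)], 3), "\n")
  invisible(x)
}

#' Plasma concentration-time profile
#'
#' One subject-period arm of a crossover bioavailability study.  Values below
#' the lower limit of quantitation (LLOQ) are flagged, never dropped or
#' overwritten; fitting routines ignore flagged entries.
#'
#' @param subject_id subject label.
#' @param period crossover period (integer).
#' @param regimen regimen label (the IR reference or an ER formulation id).
#' @param dose_mg administered dose in mg.
#' @param times sampling times in hours post-dose, nonnegative, strictly
#'   increasing.
#' @param concentrations plasma concentrations in ng/mL, nonnegative.
#' @param lloq lower limit of quantitation in ng/mL; entries strictly below it
#'   are flagged as BLQ.
#' @return an object of class `pk_profile` with a logical `blq` element.
#' @export
pk_profile <- function(subject_id, period, regimen, dose_mg, times,
                       concentrations, lloq = 0) {
  times <- as.numeric(times)
  concentrations <- as.numeric(concentrations)
  if (length(times) != length(concentrations))
    stop("times and concentrations differ in length")
  check_times(times, "sampling times")
  if (any(is.na(concentrations)) || any(concentrations < 0))
    stop("concentrations must be nonnegative and non-missing")
  if (!is.numeric(dose_mg) || dose_mg <= 0) stop("dose_mg must be positive")
  structure(
    list(subject_id = as.character(subject_id),
         period = as.integer(period),
         regimen = as.character(regimen),
         dose_mg = as.numeric(dose_mg),
         times = times,
         concentrations = concentrations,
         blq = concentrations < lloq,
         lloq = as.numeric(lloq)),
    class = "pk_profile")
}

#' @export
print.pk_profile <- function(x, ...) {
  cat("PK profile: subject", x$subject_id, "period", x$period,
      "regimen", x$regimen, sprintf("(%g mg)\n", x$dose_mg))
  cat(" ", length(x$times), "samples over", max(x$times), "h;",
      sum(x$blq), "below LLOQ of", x$lloq, "ng/mL\n")
  invisible(x)
}

# quantifiable portion of a profile used by fitting routines; leading BLQ
# samples (before the first quantifiable one) are returned as zeros when
# keep_leading_zero is TRUE (standard NCA convention), embedded/trailing BLQ
# samples are excluded.
quantifiable <- function(profile, keep_leading_zero = FALSE) {
  q <- !profile$blq
  t <- profile$times
  y <- profile$concentrations
  if (!any(q)) return(list(times = numeric(0), conc = numeric(0)))
  first_q <- which(q)[1]
  keep <- q
  if (keep_leading_zero && first_q > 1) {
    lead <- seq_len(first_q - 1L)
    keep[lead] <- TRUE
    y[lead] <- 0
  }
  list(times = t[keep], conc = y[keep])
}

#' Crossover study dataset
#'
#' Bundle of plasma profiles and dissolution profiles plus the arm roles:
#' which regimen is the IR reference and which ER formulations are used for
#' model building (internal) versus external validation.
#'
#' @param profiles list of [pk_profile] objects.
#' @param dissolution list of [dissolution_profile] objects.
#' @param reference_regimen label of the IR reference arm.
#' @param internal character vector of internal (model-building) formulations.
#' @param external character vector of external validation formulations.
#' @return an object of class `study_dataset`.
#' @details Invariants enforced: the reference regimen appears exactly once
#'   per subject, and every subject contributing an ER profile also has a
#'   reference profile (the unit impulse response is per-subject, so an ER
#'   arm without its own reference arm cannot be deconvolved).
#' @export
study_dataset <- function(profiles, dissolution = list(),
                          reference_regimen, internal = NULL, external = NULL) {
  stopifnot(is.list(profiles), is.list(dissolution))
  subj <- vapply(profiles, `[[`, character(1), "subject_id")
  regi <- vapply(profiles, `[[`, character(1), "regimen")
  ref <- regi == reference_regimen
  nref <- table(factor(subj[ref], levels = unique(subj)))
  if (any(nref > 1))
    stop("reference regimen appears more than once for subject(s): ",
         paste(names(nref)[nref > 1], collapse = ", "))
  er_subj <- unique(subj[!ref])
  missing_ref <- setdiff(er_subj, subj[ref])
  if (length(missing_ref))
    stop("subject(s) with ER data but no reference arm: ",
         paste(missing_ref, collapse = ", "))
  forms <- setdiff(unique(regi), reference_regimen)
  if (is.null(internal) && is.null(external)) { internal <- forms; external <- character(0) }
  if (is.null(internal)) internal <- setdiff(forms, external)
  if (is.null(external)) external <- setdiff(forms, internal)
  structure(
    list(profiles = profiles,
         dissolution = dissolution,
         reference_regimen = reference_regimen,
         internal_formulations = internal,
         external_formulations = external),
    class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  subj <- unique(vapply(x$profiles, `[[`, character(1), "subject_id"))
  regi <- unique(vapply(x$profiles, `[[`, character(1), "regimen"))
  cat("Crossover study dataset:", length(x$profiles), "profiles,",
      length(subj), "subjects,", length(regi), "regimens\n")
  cat("  reference:", x$reference_regimen,
      " internal:", paste(x$internal_formulations, collapse = ", "),
      " external:", paste(x$external_formulations, collapse = ", "), "\n")
  cat("  dissolution profiles:", length(x$dissolution), "\n")
  invisible(x)
}

#' Select plasma profiles from a study dataset
#'
#' @param dataset a [study_dataset].
#' @param regimen,subject optional filters (character vectors).
#' @return list of [pk_profile] objects.
#' @export
dataset_profiles <- function(dataset, regimen = NULL, subject = NULL) {
  keep <- rep(TRUE, length(dataset$profiles))
  if (!is.null(regimen))
    keep <- keep & vapply(dataset$profiles, `[[`, character(1), "regimen") %in% regimen
  if (!is.null(subject))
    keep <- keep & vapply(dataset$profiles, `[[`, character(1), "subject_id") %in% subject
  dataset$profiles[keep]
}

#' Select dissolution profiles for one formulation
#'
#' @param dataset a [study_dataset].
#' @param formulation formulation label.
#' @return list of [dissolution_profile] objects (replicates).
#' @export
dataset_dissolution <- function(dataset, formulation) {
  hit <- vapply(dataset$dissolution, `[[`, character(1), "formulation_id") == formulation
  if (!any(hit)) stop("no dissolution profile for formulation ", formulation)
  dataset$dissolution[hit]
}
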