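#' Read dissolution profiles from a CSV file
#'
#' Expects a long-format delimited file with one row per (formulation,
#' replicate, time) holding cumulative percent dissolved.  Percent is
#' converted to fraction; rows are grouped into one [dissolution_profile]
#' per formulation/replicate combination.
#'
#' @param path file path.
#' @param layout named character vector mapping the roles `formulation`,
#'   `time`, `pct_dissolved` (and optionally `replicate`, `hpmc_pct`) to
#'   column names in the file.
#' @param sep field separator, default comma.
#' @return list of [dissolution_profile] objects.
#' @export
read_dissolution <- function(path,
                             layout = c(formulation = "formulation",
                                        time = "time_h",
                                        pct_dissolved = "pct_dissolved"),
                             sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  layout <- as.list(layout)
  required <- c("formulation", "time", "pct_dissolved")
  for (role in required) {
    col <- layout[[role]]
    if (is.null(col) || !col %in% names(df))
      stop("missing column '", if (is.null(col)) role else col, "' in ", path)
  }
  rep_col <- layout[["replicate"]]
  hpmc_col <- layout[["hpmc_pct"]]
  key <- df[[layout[["formulation"]]]]
  if (!is.null(rep_col) && rep_col %in% names(df))
    key <- paste(key, df[[rep_col]], sep = "\r")
  out <- lapply(split(seq_len(nrow(df)), key), function(idx) {
    rows <- df[idx, , drop = FALSE]
    ord <- order(rows[[layout[["time"]]]])
    rows <- rows[ord, , drop = FALSE]
    t <- rows[[layout[["time"]]]]
    if (anyDuplicated(t)) {
      dup <- which(duplicated(t))[1]
      stop("duplicate time ", t[dup], " h for formulation ",
           rows[[layout[["formulation"]]]][1], " (file row ", idx[ord][dup], ")")
    }
    dissolution_profile(
      formulation_id = rows[[layout[["formulation"]]]][1],
      times = t,
      fraction_dissolved = rows[[layout[["pct_dissolved"]]]] / 100,
      hpmc_pct = if (!is.null(hpmc_col) && hpmc_col %in% names(rows))
        rows[[hpmc_col]][1] else NA_real_,
      replicate_id = if (!is.null(rep_col) && rep_col %in% names(rows))
        rows[[rep_col]][1] else NULL)
  })
  names(out) <- NULL
  out
}

#' Read crossover plasma concentration data from a CSV file
#'
#' Expects long format with columns subject, period, regimen, dose_mg,
#' time_h, conc_ng_ml.  Concentrations below `lloq` are flagged (not
#' dropped).  Returns a [study_dataset]; its invariants (one reference arm
#' per subject, no orphan ER arms) are enforced on read.
#'
#' @param path file path.
#' @param reference_regimen label of the IR reference regimen.
#' @param lloq lower limit of quantitation in ng/mL.
#' @param internal,external optional formulation role assignment, see
#'   [study_dataset].
#' @param dissolution optional list of [dissolution_profile] objects to attach.
#' @param sep field separator.
#' @return a [study_dataset].
#' @export
read_concentrations <- function(path, reference_regimen, lloq = 0.05,
                                internal = NULL, external = NULL,
                                dissolution = list(), sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  needed <- c("subject", "period", "regimen", "dose_mg", "time_h", "conc_ng_ml")
  miss <- setdiff(needed, names(df))
  if (length(miss)) stop("missing column(s) ", paste(miss, collapse = ", "), " in ", path)
  key <- paste(df$subject, df$period, df$regimen, sep = "\r")
  profiles <- lapply(split(seq_len(nrow(df)), key), function(idx) {
    rows <- df[idx, , drop = FALSE]
    rows <- rows[order(rows$time_h), , drop = FALSE]
    pk_profile(subject_id = rows$subject[1], period = rows$period[1],
               regimen = rows$regimen[1], dose_mg = rows$dose_mg[1],
               times = rows$time_h, concentrations = rows$conc_ng_ml,
               lloq = lloq)
  })
  names(profiles) <- NULL
  study_dataset(profiles, dissolution = dissolution,
                reference_regimen = reference_regimen,
                internal = internal, external = external)
}

#' Write a study dataset to CSV files
#'
#' Inverse of [read_concentrations] / [read_dissolution]: writes the plasma
#' data (and, when present, the dissolution data) in the canonical long
#' format, at full precision so that a read round-trip reproduces the
#' dataset exactly.
#'
#' @param dataset a [study_dataset].
#' @param conc_path output path for the concentration CSV.
#' @param diss_path optional output path for the dissolution CSV.
#' @return invisibly, the concentration data frame.
#' @export
write_study <- function(dataset, conc_path, diss_path = NULL) {
  conc <- do.call(rbind, lapply(dataset$profiles, function(p)
    data.frame(subject = p$subject_id, period = p$period, regimen = p$regimen,
               dose_mg = p$dose_mg, time_h = p$times,
               conc_ng_ml = p$concentrations)))
  utils::write.csv(fmt_numeric_cols(conc, "%.17g"), conc_path,
                   row.names = FALSE, quote = FALSE)
  if (!is.null(diss_path) && length(dataset$dissolution)) {
    diss <- do.call(rbind, lapply(dataset$dissolution, function(d)
      data.frame(formulation = d$formulation_id, time_h = d$times,
                 pct_dissolved = 100 * d$fraction_dissolved,
                 hpmc_pct = d$hpmc_pct, replicate = d$replicate_id)))
    utils::write.csv(fmt_numeric_cols(diss, "%.17g"), diss_path,
                     row.names = FALSE, quote = FALSE)
  }
  invisible(conc)
}

# render numeric columns at full precision without padding (format() pads)
fmt_numeric_cols <- function(df, fmt) {
  for (j in seq_along(df))
    if (is.numeric(df[[j]])) df[[j]] <- sprintf(fmt, df[[j]])
  df
}

#' Write a validation report to disk
#'
#' Writes the machine-readable prediction-error table as CSV (columns:
#' formulation, parameter, observed, predicted, pe_pct, criterion, pass)
#' and a human-readable text summary alongside it.  Output is deterministic:
#' identical reports produce bit-identical files.
#'
#' @param report an `ivivc_validation` object (see [validate_ivivc]).
#' @param path output CSV path; the text summary is written to the same path
#'   with extension `.txt`.
#' @return invisibly, the table written.
#' @export
write_report <- function(report, path) {
  tab <- as.data.frame(report)
  utils::write.csv(fmt_numeric_cols(tab, "%.15g"), path,
                   row.names = FALSE, quote = FALSE)
  txt_path <- paste0(sub("\\.[Cc][Ss][Vv]$", "", path), ".txt")
  con <- file(txt_path, open = "wt")
  on.exit(close(con))
  writeLines(utils::capture.output(print(report)), con)
  invisible(tab)
}
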