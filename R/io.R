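BATCH_COLUMNS <- c("sample_id", "batch_id", "role", "level_label",
                   "nominal_conc", "analyte_area", "is_area", "matrix_lot",
                   "condition_tag", "dilution_factor")
BATCH_ROLES <- c("STD", "QC", "BLANK", "DOUBLE_BLANK", "SPVS", "STABILITY",
                 "MATRIX_EFFECT", "UNKNOWN")
PROFILE_COLUMNS <- c("subject_id", "route", "dose_mg_per_kg", "mw",
                     "time_min", "conc_ng_per_ml", "lloq")

#' Read a batch of peak-area records from CSV
#'
#' The batch format is comma-separated UTF-8 with a header row and one sample
#' per line, columns `sample_id, batch_id, role, level_label, nominal_conc,
#' analyte_area, is_area, matrix_lot, condition_tag, dilution_factor`. Empty
#' cells mean "absent" and are distinct from zero: a blank analyte area of 0
#' is a real measurement, an empty `is_area` means no internal standard was
#' spiked (double blanks). Roles are `STD`, `QC`, `BLANK`, `DOUBLE_BLANK`,
#' `SPVS`, `STABILITY`, `MATRIX_EFFECT` or `UNKNOWN`; `STD` and `QC` rows
#' require a nominal concentration. Malformed rows are reported with their
#' line number.
#'
#' @param path CSV file path.
#' @return data frame of validated batch records.
#' @export
read_batch_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                        colClasses = "character")
  missing_cols <- setdiff(BATCH_COLUMNS, names(df))
  if (length(missing_cols))
    stop_quantpk(path, ": missing required column(s) ",
                 paste(missing_cols, collapse = ", "))
  df <- df[BATCH_COLUMNS]
  for (col in c("nominal_conc", "analyte_area", "is_area", "dilution_factor")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- is.na(v) & !is.na(df[[col]])
    if (any(bad))
      stop_quantpk(path, ": non-numeric ", col, " on line ", which(bad)[1] + 1)
    df[[col]] <- v
  }
  df$dilution_factor[is.na(df$dilution_factor)] <- 1
  row_no <- seq_len(nrow(df)) + 1   # header is line 1

  bad_role <- !df$role %in% BATCH_ROLES
  if (any(bad_role))
    stop_quantpk(path, ": unknown role '", df$role[bad_role][1],
                 "' on line ", row_no[bad_role][1])
  bad_area <- !is.na(df$analyte_area) & df$analyte_area < 0
  if (any(bad_area))
    stop_quantpk(path, ": negative analyte area on line ", row_no[bad_area][1])
  bad_is <- !is.na(df$is_area) & df$is_area < 0
  if (any(bad_is))
    stop_quantpk(path, ": negative internal-standard area on line ", row_no[bad_is][1])
  need_nom <- df$role %in% c("STD", "QC") & is.na(df$nominal_conc)
  if (any(need_nom))
    stop_quantpk(path, ": STD/QC row without nominal concentration on line ",
                 row_no[need_nom][1])
  if (any(df$dilution_factor < 1))
    stop_quantpk(path, ": dilution_factor must be >= 1 (line ",
                 row_no[df$dilution_factor < 1][1], ")")
  dup <- duplicated(df[, c("batch_id", "sample_id")])
  if (any(dup))
    stop_quantpk(path, ": duplicate sample_id '", df$sample_id[dup][1],
                 "' within batch '", df$batch_id[dup][1], "' on line ",
                 row_no[dup][1])
  df
}

#' Write batch records to CSV
#'
#' Inverse of [read_batch_csv()]; `NA` cells are written empty.
#'
#' @param records data frame of batch records.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_batch_csv <- function(records, path) {
  missing_cols <- setdiff(BATCH_COLUMNS, names(records))
  if (length(missing_cols))
    stop_quantpk("records are missing column(s) ", paste(missing_cols, collapse = ", "))
  utils::write.csv(records[BATCH_COLUMNS], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read concentration-time profiles from CSV
#'
#' Long format, one observation per line, columns `subject_id, route,
#' dose_mg_per_kg, mw, time_min, conc_ng_per_ml, lloq`. The concentration
#' cell may hold the literal token `BLQ` (below the limit of
#' quantification), which is stored as 0 — kept distinct from a numeric 0
#' in the file so censoring is explicit. Times must be strictly increasing
#' within a subject and dosing metadata constant.
#'
#' @param path CSV file path.
#' @return list of [conc_time_profile] objects, one per subject.
#' @export
read_profile_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                        colClasses = "character")
  missing_cols <- setdiff(PROFILE_COLUMNS, names(df))
  if (length(missing_cols))
    stop_quantpk(path, ": missing required column(s) ",
                 paste(missing_cols, collapse = ", "))
  conc <- ifelse(trimws(df$conc_ng_per_ml) == "BLQ", "0", df$conc_ng_per_ml)
  conc <- suppressWarnings(as.numeric(conc))
  if (any(is.na(conc)))
    stop_quantpk(path, ": non-numeric concentration on line ",
                 which(is.na(conc))[1] + 1)
  num <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (any(is.na(v)))
      stop_quantpk(path, ": non-numeric ", col, " on line ", which(is.na(v))[1] + 1)
    v
  }
  time_min <- num("time_min"); dose <- num("dose_mg_per_kg")
  mw <- num("mw"); lloq <- num("lloq")

  lapply(split(seq_len(nrow(df)), df$subject_id)[unique(df$subject_id)],
         function(idx) {
    idx <- idx[order(time_min[idx])]
    if (any(duplicated(time_min[idx])))
      stop_quantpk(path, ": duplicate time for subject '", df$subject_id[idx[1]], "'")
    if (length(unique(df$route[idx])) > 1 || length(unique(dose[idx])) > 1 ||
        length(unique(mw[idx])) > 1)
      stop_quantpk(path, ": subject '", df$subject_id[idx[1]],
                   "' has inconsistent route/dose/MW")
    conc_time_profile(df$subject_id[idx[1]], route = df$route[idx[1]],
                      dose = dose[idx[1]], mw = mw[idx[1]],
                      times = time_min[idx], conc = conc[idx],
                      lloq = lloq[idx[1]])
  })
}

#' Write concentration-time profiles to CSV
#'
#' Inverse of [read_profile_csv()]. Stored zeros are written as the `BLQ`
#' token whenever the profile has a positive LLOQ.
#'
#' @param profiles list of [conc_time_profile] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profiles, path) {
  if (inherits(profiles, "conc_time_profile")) profiles <- list(profiles)
  rows <- do.call(rbind, lapply(profiles, function(p) {
    conc <- as.character(p$conc)
    if (p$lloq > 0) conc[p$conc == 0] <- "BLQ"
    data.frame(subject_id = p$subject_id, route = p$route,
               dose_mg_per_kg = p$dose, mw = p$mw,
               time_min = p$times, conc_ng_per_ml = conc, lloq = p$lloq)
  }))
  utils::write.csv(rows, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Run configuration
#'
#' Collects every tunable of the pipeline in one place: the calibration model
#' and response basis, all acceptance limits (percent), terminal-slope and
#' AUC options, and the seed. Defaults are the regulatory conventions: 15%
#' QC limit with 20% at the LLOQ, and 15% for matrix-factor variability,
#' stability and cross-matrix validation.
#'
#' @param model_kind,response_basis see [fit_calibration()].
#' @param qc_limit,lloq_limit,mf_cv_limit,stability_limit,crossval_limit
#'   acceptance limits in percent, all positive.
#' @param auc_method,iv_c0,lambda_z_window see [nca_options()].
#' @param seed integer seed recorded with reports.
#' @return list of class `run_config`.
#' @export
run_config <- function(model_kind = "wagner", response_basis = "area_ratio",
                       qc_limit = 15, lloq_limit = 20, mf_cv_limit = 15,
                       stability_limit = 15, crossval_limit = 15,
                       auc_method = "linear", iv_c0 = TRUE,
                       lambda_z_window = NULL, seed = 1L) {
  lims <- c(qc_limit, lloq_limit, mf_cv_limit, stability_limit, crossval_limit)
  if (any(lims <= 0)) stop_quantpk("all acceptance limits must be positive")
  structure(list(model_kind = model_kind, response_basis = response_basis,
                 qc_limit = qc_limit, lloq_limit = lloq_limit,
                 mf_cv_limit = mf_cv_limit, stability_limit = stability_limit,
                 crossval_limit = crossval_limit, auc_method = auc_method,
                 iv_c0 = iv_c0, lambda_z_window = lambda_z_window,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read or write a run configuration as structured text (DCF)
#'
#' @param path file path.
#' @return for the reader, a [run_config()]; the writer returns `path`
#'   invisibly.
#' @export
read_run_config <- function(path) {
  d <- as.list(as.data.frame(read.dcf(path), stringsAsFactors = FALSE))
  defaults <- run_config()
  num_fields <- c("qc_limit", "lloq_limit", "mf_cv_limit", "stability_limit",
                  "crossval_limit", "seed")
  args <- list()
  for (nm in names(d)) {
    if (!nm %in% names(defaults)) stop_quantpk(path, ": unknown config field '", nm, "'")
    args[[nm]] <- if (nm %in% num_fields) as.numeric(d[[nm]])
                  else if (nm == "iv_c0") as.logical(d[[nm]])
                  else if (nm == "lambda_z_window")
                    as.numeric(strsplit(d[[nm]], ",")[[1]])
                  else d[[nm]]
  }
  do.call(run_config, args)
}

#' @rdname read_run_config
#' @param config a [run_config()].
#' @export
write_run_config <- function(config, path) {
  flat <- config
  flat$lambda_z_window <- if (is.null(config$lambda_z_window)) NULL
                          else paste(config$lambda_z_window, collapse = ",")
  write.dcf(as.data.frame(flat[!vapply(flat, is.null, logical(1))]), path)
  invisible(path)
}

log_stage <- function(stage, ...) {
  message(sprintf("[quantpk:%s] %s", stage, paste0(...)))
}
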