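#' Run the full method-validation analysis over one or more batches
#'
#' Orchestrates the validation pipeline: per batch, fits the calibration
#' curve on its standards, back-calculates standards and QCs against that
#' batch's curve, and pools the results: a cumulative calibration-standards
#' table, intra- and inter-batch QC accuracy/precision, blank specificity,
#' and — when records tagged for them are present — extraction recovery,
#' matrix effect, stability panels and cross-matrix validation.
#'
#' Optional analyses are recognised by `condition_tag`: recovery uses
#' `recovery_extracted` vs `recovery_reference`; matrix effect uses
#' `with_matrix` vs `without_matrix` on `MATRIX_EFFECT` rows (evaluated per
#' level); stability uses `STABILITY` rows whose tag names the condition
#' (`stock_rt`, `stock_5c`, `stock_m20c` compared with `stock_fresh` by peak
#' area; `long_term`, `freeze_thaw`, `on_bench` compared with nominal after
#' back-calculation; `on_instrument` compared with `ois_reference` after
#' back-calculation); cross-validation uses QC rows tagged `cross_matrix`,
#' quantified against the primary-matrix curve of their batch.
#'
#' @param batches a batch record data frame, a list of them, or a character
#'   vector of CSV paths for [read_batch_csv()].
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, report CSVs mirroring the
#'   result tables, the serialized calibration fits (DCF) and a summary
#'   record with all pass flags are written there.
#' @return (invisibly) list with `fits`, `calibration`, `qc` (intra/inter),
#'   `specificity`, `recovery`, `matrix_effect`, `stability`,
#'   `cross_validation` and `summary` (named logical pass flags).
#' @export
run_validation <- function(batches, config = run_config(), out_dir = NULL) {
  records <- normalize_batches(batches)
  std <- records[records$role == "STD" & is.na(records$condition_tag), , drop = FALSE]
  if (nrow(std) == 0) stop_quantpk("validation requires at least one batch with standards")
  batch_ids <- unique(std$batch_id)

  log_stage("calibration", "fitting ", length(batch_ids), " batch curve(s), model=",
            config$model_kind, ", basis=", config$response_basis)
  fits <- lapply(batch_ids, function(b) {
    fit_calibration(std[std$batch_id == b, ], model_kind = config$model_kind,
                    response_basis = config$response_basis)
  })
  names(fits) <- batch_ids

  bc <- function(rows) {            # back-calculate against each row's batch fit
    out <- rep(NA_real_, nrow(rows))
    for (b in unique(rows$batch_id)) {
      fit <- fits[[b]]
      if (is.null(fit)) stop_quantpk("batch '", b, "' has no calibration standards")
      sel <- rows$batch_id == b
      out[sel] <- back_calculate(fit, calibration_response(rows[sel, ], fit$response_basis),
                                 dilution_factor = rows$dilution_factor[sel])
    }
    out
  }

  std$conc <- bc(std)
  calib <- do.call(rbind, lapply(sort(unique(std$nominal_conc)), function(nm) {
    sel <- std$nominal_conc == nm
    cbind(data.frame(level_label = std$level_label[sel][1], nominal_conc = nm),
          level_stats(std$conc[sel], nm))
  }))
  log_stage("calibration", "pooled standards table: ", nrow(calib), " levels, mean r2 = ",
            signif(mean(vapply(fits, `[[`, numeric(1), "r_squared")), 6))

  qc_rows <- records[records$role == "QC" & (is.na(records$condition_tag) |
                       records$condition_tag == ""), , drop = FALSE]
  qc_stats <- NULL
  if (nrow(qc_rows)) {
    qc_rows$conc <- bc(qc_rows)
    qc_stats <- batch_and_run_statistics(qc_rows, qc_limit = config$qc_limit,
                                         lloq_limit = config$lloq_limit)
    log_stage("qc", "inter-batch QC stats at ", nrow(qc_stats$inter), " levels; pass: ",
              all(qc_stats$inter$pass))
  }

  blanks <- records[records$role == "BLANK", , drop = FALSE]
  spec <- NULL
  if (nrow(blanks)) {
    lloq_rec <- std[std$nominal_conc == min(std$nominal_conc), , drop = FALSE]
    spec <- check_specificity(blanks, lloq_rec, check_is = FALSE)
    log_stage("specificity", nrow(spec), " blanks checked; pass: ", all(spec$pass))
  }

  rec_ext <- records[records$condition_tag %in% "recovery_extracted", , drop = FALSE]
  rec_ref <- records[records$condition_tag %in% "recovery_reference", , drop = FALSE]
  recovery <- NULL
  if (nrow(rec_ext) && nrow(rec_ref)) {
    recovery <- absolute_recovery(rec_ext, rec_ref)
    log_stage("recovery", "mean recovery ", round_half_up(mean(recovery$recovery_pct), 1), "%")
  }

  me_w <- records[records$condition_tag %in% "with_matrix", , drop = FALSE]
  me_f <- records[records$condition_tag %in% "without_matrix", , drop = FALSE]
  me <- NULL
  if (nrow(me_w) && nrow(me_f)) {
    me <- do.call(rbind, lapply(unique(me_w$level_label), function(lv) {
      r <- matrix_factor(me_w[me_w$level_label == lv, ],
                         me_f[me_f$level_label == lv, ],
                         cv_limit = config$mf_cv_limit)
      data.frame(level_label = lv, mean_mf = r$mean_mf, pct_cv_mf = r$pct_cv_mf,
                 pass = r$pass, interpretation = r$interpretation)
    }))
    log_stage("matrix_effect", "IS-MF %CV: ",
              paste(round_half_up(me$pct_cv_mf, 1), collapse = ", "))
  }

  stab_rows <- records[records$role == "STABILITY", , drop = FALSE]
  stability <- NULL
  if (nrow(stab_rows)) {
    stability <- assess_stability_rows(stab_rows, bc, config$stability_limit)
    if (!is.null(stability))
      log_stage("stability", nrow(stability), " condition(s); pass: ", all(stability$pass))
  }

  cv_rows <- records[records$role == "QC" &
                       records$condition_tag %in% "cross_matrix", , drop = FALSE]
  crossval <- NULL
  if (nrow(cv_rows)) {
    cv_rows$conc <- bc(cv_rows)
    crossval <- cross_validate(cv_rows, limit = config$crossval_limit)
    log_stage("cross_validation", "pass: ", crossval$pass)
  }

  summary_flags <- c(
    qc = if (is.null(qc_stats)) NA else all(qc_stats$inter$pass),
    specificity = if (is.null(spec)) NA else all(spec$pass),
    matrix_effect = if (is.null(me)) NA else all(me$pass),
    stability = if (is.null(stability)) NA else all(stability$pass),
    cross_validation = if (is.null(crossval)) NA else crossval$pass)

  result <- list(fits = fits, calibration = calib, qc = qc_stats,
                 specificity = spec, recovery = recovery, matrix_effect = me,
                 stability = stability, cross_validation = crossval,
                 summary = summary_flags)
  if (!is.null(out_dir)) write_validation_reports(result, config, out_dir)
  invisible(result)
}

# stability conditions: stock_* are raw-area comparisons against stock_fresh;
# long_term / freeze_thaw / on_bench are back-calculated vs nominal;
# on_instrument is end-of-run vs the ois_reference set, back-calculated
assess_stability_rows <- function(stab, bc, limit) {
  tags <- unique(stab$condition_tag)
  rows <- list()
  fresh <- stab[stab$condition_tag %in% "stock_fresh", , drop = FALSE]
  for (tag in intersect(c("stock_rt", "stock_5c", "stock_m20c"), tags)) {
    if (!nrow(fresh)) stop_quantpk("stock stability requires 'stock_fresh' reference rows")
    rows[[tag]] <- stability_assessment(
      stab$analyte_area[stab$condition_tag == tag], mode = "pct_reference",
      reference = fresh$analyte_area, condition = tag, limit = limit)
  }
  for (tag in intersect(c("long_term", "freeze_thaw", "on_bench"), tags)) {
    sub <- stab[stab$condition_tag == tag, , drop = FALSE]
    for (nm in unique(sub$nominal_conc)) {
      sel <- sub[sub$nominal_conc == nm, , drop = FALSE]
      rows[[paste(tag, nm)]] <- stability_assessment(
        bc(sel), mode = "pct_bias_vs_nominal", nominal = nm,
        condition = sprintf("%s@%g", tag, nm), limit = limit)
    }
  }
  if ("on_instrument" %in% tags) {
    ref <- stab[stab$condition_tag %in% "ois_reference", , drop = FALSE]
    if (!nrow(ref)) stop_quantpk("on-instrument stability requires 'ois_reference' rows")
    sub <- stab[stab$condition_tag == "on_instrument", , drop = FALSE]
    for (nm in unique(sub$nominal_conc)) {
      rows[[paste("on_instrument", nm)]] <- stability_assessment(
        bc(sub[sub$nominal_conc == nm, , drop = FALSE]),
        mode = "pct_difference_vs_reference_set",
        reference = bc(ref[ref$nominal_conc == nm, , drop = FALSE]),
        condition = sprintf("on_instrument@%g", nm), limit = limit)
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

write_validation_reports <- function(result, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) if (!is.null(df))
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE, na = "")
  wr(result$calibration, "calibration_standards.csv")
  if (!is.null(result$qc)) {
    wr(result$qc$intra, "qc_intra_batch.csv")
    wr(result$qc$inter, "qc_inter_batch.csv")
  }
  wr(result$specificity, "specificity.csv")
  wr(result$recovery, "recovery.csv")
  wr(result$matrix_effect, "matrix_effect.csv")
  wr(result$stability, "stability.csv")
  if (!is.null(result$cross_validation))
    wr(result$cross_validation$per_level, "cross_validation.csv")
  fitdf <- do.call(rbind, lapply(names(result$fits), function(b) {
    f <- result$fits[[b]]
    data.frame(batch_id = b, model_kind = f$model_kind,
               response_basis = f$response_basis, coeff_a = f$coeff_a,
               coeff_b = f$coeff_b, coeff_c = f$coeff_c, lloq = f$lloq,
               uloq = f$uloq, r_squared = f$r_squared, n_points = f$n_points)
  }))
  write.dcf(fitdf, file.path(out_dir, "calibration_fits.dcf"))
  write.dcf(as.data.frame(as.list(result$summary)),
            file.path(out_dir, "summary.dcf"))
  invisible(out_dir)
}

#' Run non-compartmental analysis and bioavailability over a study
#'
#' Groups profiles into arms by route and dose, runs [compute_nca()] per
#' subject and on each arm's [mean_profile()], and pairs oral with IV arms
#' in descending dose order (high with high, low with low) to compute
#' dose-normalized oral bioavailability from the mean-profile AUC(0-inf).
#' With no IV arm, bioavailability is skipped with a logged reason.
#'
#' @param profiles a list of [conc_time_profile] objects, a `pk_study` from
#'   [simulate_study()], or a character vector of CSV paths for
#'   [read_profile_csv()].
#' @param config a [run_config()].
#' @param out_dir optional directory for the report CSVs (per-subject NCA,
#'   mean-profile NCA, bioavailability).
#' @return (invisibly) list with `per_subject` and `mean_profiles` data
#'   frames and `bioavailability` (or `NULL`).
#' @export
run_nca <- function(profiles, config = run_config(), out_dir = NULL) {
  profiles <- normalize_profiles(profiles)
  opts <- nca_options(auc_method = config$auc_method, iv_c0 = config$iv_c0,
                      lambda_z_window = config$lambda_z_window)
  key <- vapply(profiles, function(p) sprintf("%s_%g", p$route, p$dose), character(1))
  arms <- split(profiles, key)

  per_subject <- list(); mean_rows <- list()
  for (k in names(arms)) {
    arm <- arms[[k]]
    log_stage("nca", "arm ", k, ": ", length(arm), " profile(s)")
    for (p in arm) {
      r <- tryCatch(as.data.frame(compute_nca(p, opts)), error = function(e) {
        log_stage("nca", "subject ", p$subject_id, " skipped: ", conditionMessage(e))
        NULL
      })
      per_subject[[length(per_subject) + 1]] <- r
    }
    mp <- mean_profile(arm)
    mean_rows[[k]] <- as.data.frame(compute_nca(mp, opts))
  }
  per_subject <- do.call(rbind, per_subject)
  mean_tab <- do.call(rbind, mean_rows)
  rownames(mean_tab) <- NULL

  fres <- NULL
  po <- mean_tab[mean_tab$route == "PO", , drop = FALSE]
  iv <- mean_tab[mean_tab$route == "IV", , drop = FALSE]
  if (nrow(po) && nrow(iv)) {
    po <- po[order(-po$dose_mg_per_kg), , drop = FALSE]
    iv <- iv[order(-iv$dose_mg_per_kg), , drop = FALSE]
    n_pairs <- min(nrow(po), nrow(iv))
    fres <- do.call(rbind, lapply(seq_len(n_pairs), function(i) {
      f <- bioavailability(po$auc_inf_min_umol_l[i], po$dose_mg_per_kg[i],
                           iv$auc_inf_min_umol_l[i], iv$dose_mg_per_kg[i])
      data.frame(dose_oral_mg_per_kg = f$dose_oral, dose_iv_mg_per_kg = f$dose_iv,
                 auc_oral_min_umol_l = f$auc_oral, auc_iv_min_umol_l = f$auc_iv,
                 f_pct = f$f_pct)
    }))
    log_stage("bioavailability", "F = ",
              paste(round_half_up(fres$f_pct, 1), collapse = "%, "), "%")
  } else {
    log_stage("bioavailability", "skipped: need both an oral and an IV arm")
  }

  result <- list(per_subject = per_subject, mean_profiles = mean_tab,
                 bioavailability = fres)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(per_subject, file.path(out_dir, "nca_per_subject.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(mean_tab, file.path(out_dir, "nca_mean_profiles.csv"),
                     row.names = FALSE, na = "")
    if (!is.null(fres))
      utils::write.csv(fres, file.path(out_dir, "bioavailability.csv"),
                       row.names = FALSE, na = "")
  }
  invisible(result)
}

normalize_batches <- function(batches) {
  if (is.character(batches))
    batches <- lapply(batches, read_batch_csv)
  if (is.data.frame(batches)) batches <- list(batches)
  do.call(rbind, batches)
}

normalize_profiles <- function(profiles) {
  if (inherits(profiles, "pk_study"))
    return(unlist(lapply(profiles$arms, `[[`, "profiles"), recursive = FALSE))
  if (is.character(profiles))
    return(unlist(lapply(profiles, read_profile_csv), recursive = FALSE))
  if (inherits(profiles, "conc_time_profile")) return(list(profiles))
  profiles
}
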