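#' Accuracy and precision statistics for one concentration level
#'
#' The core summary used throughout method validation: arithmetic mean,
#' accuracy as percent of nominal (%Nom), precision as percent coefficient of
#' variation (%CV, sample standard deviation with the n-1 denominator), and
#' %Bias = %Nom - 100.
#'
#' @param values back-calculated concentrations (ng/ml) or, for
#'   stock-solution panels, raw peak areas.
#' @param nominal the nominal (true) value the level was spiked at; must be
#'   positive.
#' @return one-row data frame with columns `n`, `mean`, `pct_nom`, `pct_cv`,
#'   `pct_bias`. `pct_cv` is `NA` when fewer than two values are supplied.
#' @export
#' @examples
#' level_stats(c(4.1, 3.9, 4.2), nominal = 3.91)
level_stats <- function(values, nominal) {
  if (length(values) < 1) stop_quantpk("level_stats needs at least one value")
  if (!is.finite(nominal) || nominal <= 0)
    stop_quantpk("nominal must be a positive number")
  m <- mean(values)
  pct_nom <- 100 * m / nominal
  data.frame(n = length(values), mean = m,
             pct_nom = pct_nom, pct_cv = pct_cv_of(values),
             pct_bias = pct_nom - 100)
}

#' Intra- and inter-batch accuracy and precision
#'
#' Summarises replicate quality-control results per (batch, level) and,
#' pooled across batches, per level — the layout of a cumulative QC table in
#' a validation report (e.g. three batches of six replicates give n = 18 per
#' level inter-batch). Each pooled level gets an acceptance flag: |%Bias| and
#' %CV within `qc_limit` percent (`lloq_limit` at the lowest level, where the
#' regulatory convention is wider).
#'
#' @param qc data frame with columns `batch_id`, `level_label`,
#'   `nominal_conc` and `conc` (back-calculated concentration, ng/ml).
#' @param qc_limit,lloq_limit acceptance limits in percent (defaults 15
#'   and 20).
#' @return list with elements `intra` (one row per batch x level) and `inter`
#'   (one row per level with logical `pass`). A level missing from a batch is
#'   simply absent from `intra`, never an error.
#' @export
batch_and_run_statistics <- function(qc, qc_limit = 15, lloq_limit = 20) {
  need <- c("batch_id", "level_label", "nominal_conc", "conc")
  if (!all(need %in% names(qc)))
    stop_quantpk("qc must have columns ", paste(need, collapse = ", "))
  if (nrow(qc) < 1) stop_quantpk("no QC records supplied")

  key_levels <- unique(qc[, c("level_label", "nominal_conc")])
  key_levels <- key_levels[order(key_levels$nominal_conc), , drop = FALSE]
  lloq_nom <- min(key_levels$nominal_conc)

  intra <- do.call(rbind, lapply(unique(qc$batch_id), function(b) {
    sub <- qc[qc$batch_id == b, , drop = FALSE]
    do.call(rbind, lapply(seq_len(nrow(key_levels)), function(i) {
      sel <- sub$level_label == key_levels$level_label[i]
      if (!any(sel)) return(NULL)
      cbind(data.frame(batch_id = b,
                       level_label = key_levels$level_label[i],
                       nominal_conc = key_levels$nominal_conc[i]),
            level_stats(sub$conc[sel], key_levels$nominal_conc[i]))
    }))
  }))

  inter <- do.call(rbind, lapply(seq_len(nrow(key_levels)), function(i) {
    sel <- qc$level_label == key_levels$level_label[i]
    st <- level_stats(qc$conc[sel], key_levels$nominal_conc[i])
    lim <- if (key_levels$nominal_conc[i] == lloq_nom) lloq_limit else qc_limit
    st$limit <- lim
    st$pass <- abs(st$pct_bias) <= lim & (is.na(st$pct_cv) | st$pct_cv <= lim)
    cbind(data.frame(level_label = key_levels$level_label[i],
                     nominal_conc = key_levels$nominal_conc[i]), st)
  }))
  rownames(intra) <- rownames(inter) <- NULL
  list(intra = intra, inter = inter)
}

#' Absolute extraction recovery
#'
#' Extraction efficiency per level: the mean peak area of extracted spiked
#' samples as a percentage of the mean area of post-extraction ("theoretical")
#' reference samples, with %CV taken over the extracted replicates.
#'
#' @param extracted,references data frames with columns `level_label`,
#'   `nominal_conc` and `analyte_area` (use the internal-standard areas for an
#'   IS recovery row). Each level needs at least two records per side.
#' @return data frame with one row per level: `level_label`, `nominal_conc`,
#'   `mean_extracted_area`, `mean_reference_area`, `recovery_pct`, `pct_cv`.
#' @export
absolute_recovery <- function(extracted, references) {
  levels_ <- unique(extracted[, c("level_label", "nominal_conc")])
  levels_ <- levels_[order(levels_$nominal_conc, decreasing = TRUE), , drop = FALSE]
  out <- lapply(seq_len(nrow(levels_)), function(i) {
    lab <- levels_$level_label[i]
    e <- extracted$analyte_area[extracted$level_label == lab]
    r <- references$analyte_area[references$level_label == lab]
    if (length(e) < 2 || length(r) < 2)
      stop_quantpk("level ", lab, ": at least 2 records per side are required")
    mr <- mean(r)
    if (mr <= 0) stop_quantpk("level ", lab, ": zero reference mean")
    data.frame(level_label = lab, nominal_conc = levels_$nominal_conc[i],
               mean_extracted_area = mean(e), mean_reference_area = mr,
               recovery_pct = 100 * mean(e) / mr, pct_cv = pct_cv_of(e))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Internal-standard normalized matrix factor
#'
#' Quantifies matrix effects on ionization. For each matrix lot the IS-MF is
#' the analyte/IS peak-area ratio in the presence of matrix divided by the
#' mean analyte/IS ratio of the matrix-free (neat solution) replicates. An
#' IS-MF of one means no net matrix effect; below one, ion suppression; above
#' one, enhancement. The assay is reproducible when the %CV of the lot IS-MFs
#' is at most `cv_limit` (default 15%).
#'
#' @param with_matrix data frame of matrix-present records (`matrix_lot`,
#'   `analyte_area`, `is_area`), at least one lot.
#' @param without_matrix data frame of matrix-free records (`analyte_area`,
#'   `is_area`), at least two replicates.
#' @param cv_limit acceptance limit on the %CV of lot matrix factors.
#' @return list with `per_lot` (data frame: `matrix_lot`, `is_mf`),
#'   `mean_mf`, `pct_cv_mf`, `pass` and a one-word `interpretation`
#'   ("suppression", "enhancement" or "none") from the mean.
#' @export
matrix_factor <- function(with_matrix, without_matrix, cv_limit = 15) {
  if (nrow(with_matrix) < 1) stop_quantpk("at least one matrix lot is required")
  if (nrow(without_matrix) < 2) stop_quantpk("at least two matrix-free replicates are required")
  if (any(c(with_matrix$is_area, without_matrix$is_area) <= 0, na.rm = TRUE) ||
      any(is.na(c(with_matrix$is_area, without_matrix$is_area))))
    stop_quantpk("all records need a positive internal-standard area")
  free_mean <- mean(without_matrix$analyte_area / without_matrix$is_area)
  if (free_mean <= 0) stop_quantpk("zero matrix-free mean ratio")
  mf <- (with_matrix$analyte_area / with_matrix$is_area) / free_mean
  per_lot <- data.frame(matrix_lot = with_matrix$matrix_lot %||%
                          as.character(seq_along(mf)),
                        is_mf = mf)
  cv <- pct_cv_of(mf)
  m <- mean(mf)
  list(per_lot = per_lot, mean_mf = m, pct_cv_mf = cv,
       pass = !is.na(cv) && cv <= cv_limit,
       interpretation = if (isTRUE(all.equal(m, 1, tolerance = 0.02))) "none"
                        else if (m < 1) "suppression" else "enhancement")
}

#' Stability assessment under a storage or handling condition
#'
#' Three comparison modes cover the usual stability panels:
#' * `pct_reference` — stored stock-solution areas as percent of freshly
#'   prepared stock areas (value centred on 100);
#' * `pct_bias_vs_nominal` — measured concentrations of stressed QCs against
#'   their nominal concentration (freeze-thaw, on-bench, long-term; value
#'   centred on 0);
#' * `pct_difference_vs_reference_set` — percent change of an end-of-run set
#'   against a start-of-run reference set (on-instrument stability; value
#'   centred on 0).
#'
#' The condition passes when the deviation (from 100 or from 0) is within
#' `limit` percent.
#'
#' @param test numeric vector of test measurements (areas or concentrations,
#'   mode-dependent).
#' @param mode one of `"pct_reference"`, `"pct_bias_vs_nominal"`,
#'   `"pct_difference_vs_reference_set"`.
#' @param reference numeric vector of reference measurements (required by the
#'   reference-based modes).
#' @param nominal nominal concentration (required by `pct_bias_vs_nominal`).
#' @param condition optional label (e.g. `"freeze_thaw"`, `"stock_rt"`)
#'   carried into the result.
#' @param limit acceptance limit in percent (default 15).
#' @return one-row data frame: `condition`, `comparison_mode`, `n`, `mean`,
#'   `value` (the mode's percent statistic), `pct_cv`, `pass`.
#' @export
stability_assessment <- function(test,
                                 mode = c("pct_reference", "pct_bias_vs_nominal",
                                          "pct_difference_vs_reference_set"),
                                 reference = NULL, nominal = NULL,
                                 condition = NA_character_, limit = 15) {
  mode <- match.arg(mode)
  if (length(test) < 1) stop_quantpk("empty test set")
  if (mode == "pct_bias_vs_nominal") {
    if (is.null(nominal)) stop_quantpk("pct_bias_vs_nominal requires a nominal concentration")
    st <- level_stats(test, nominal)
    value <- st$pct_bias
  } else {
    if (is.null(reference) || length(reference) < 1)
      stop_quantpk(mode, " requires a reference set")
    mref <- mean(reference)
    if (mref == 0) stop_quantpk("zero reference mean")
    value <- if (mode == "pct_reference") 100 * mean(test) / mref
             else 100 * (mean(test) - mref) / mref
  }
  centre <- if (mode == "pct_reference") 100 else 0
  data.frame(condition = condition, comparison_mode = mode,
             n = length(test), mean = mean(test), value = value,
             pct_cv = pct_cv_of(test),
             pass = abs(value - centre) <= limit)
}

#' Cross-matrix validation
#'
#' Checks that QCs prepared in an alternate matrix (e.g. mouse blood),
#' quantified against a calibration prepared in the primary matrix (e.g.
#' human blood), remain accurate: the mean accuracy at every level must be
#' within `limit` percent of nominal. A level breaching the limit is flagged,
#' not raised as an error — guidance allows wider limits when justified, so
#' the judgement is left to the analyst.
#'
#' @param records data frame with columns `level_label`, `nominal_conc` and
#'   `conc` (back-calculated against the primary-matrix curve); replicates at
#'   three or more levels are expected.
#' @param limit per-level acceptance limit on |%Bias| (default 15).
#' @return list with `per_level` (a [level_stats()] row per level plus
#'   `pass`) and the overall `pass` (all levels within the limit).
#' @export
cross_validate <- function(records, limit = 15) {
  noms <- unique(records[, c("level_label", "nominal_conc")])
  noms <- noms[order(noms$nominal_conc), , drop = FALSE]
  if (nrow(noms) < 3)
    stop_quantpk("cross-validation expects replicate QCs at >= 3 levels, got ", nrow(noms))
  per_level <- do.call(rbind, lapply(seq_len(nrow(noms)), function(i) {
    sel <- records$level_label == noms$level_label[i]
    if (!any(sel)) stop_quantpk("level ", noms$level_label[i], " has no records")
    st <- level_stats(records$conc[sel], noms$nominal_conc[i])
    st$pass <- abs(st$pct_bias) <= limit
    cbind(data.frame(level_label = noms$level_label[i],
                     nominal_conc = noms$nominal_conc[i]), st)
  }))
  rownames(per_level) <- NULL
  list(per_level = per_level, pass = all(per_level$pass))
}
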