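# --- below-limit-of-quantification handling -------------------------------
# A value is BLQ when it is below the profile's LLOQ (stored zeros included).
# Rules: BLQ before Tmax is kept as 0 (the drug genuinely is not there yet);
# BLQ between or after positive points past Tmax is excluded, so trailing
# censored samples never flatten the terminal slope.
blq_preprocess <- function(profile) {
  stopifnot(inherits(profile, "conc_time_profile"))
  conc <- profile$conc
  times <- profile$times
  blq <- conc <= 0 | conc < profile$lloq
  if (all(blq)) stop_quantpk("profile has no quantifiable concentrations")
  tmax_time <- times[!blq][which.max(conc[!blq])]
  keep <- !blq | times < tmax_time
  conc[blq] <- 0
  list(times = times[keep], conc = conc[keep])
}

#' Terminal elimination rate constant (lambda_z)
#'
#' Log-linear regression of the terminal phase. In automatic mode every
#' window of at least three positive points that starts strictly after Tmax
#' and ends at the last positive observation is fitted by ordinary least
#' squares of `ln(conc)` on time, and the window with the largest adjusted
#' r-squared wins, ties broken toward more points. An explicit time window
#' can be supplied instead when a particular choice of points is wanted.
#'
#' @param profile a [conc_time_profile].
#' @param window optional numeric length-2 time range (minutes); all positive
#'   post-preprocessing points inside it are used.
#' @return list with `lambda_z` (1/min, positive), `intercept` (ln ng/ml),
#'   `window` (the times used), `n_points` and `r2_adj`.
#' @export
fit_lambda_z <- function(profile, window = NULL) {
  d <- blq_preprocess(profile)
  pos <- which(d$conc > 0)
  tmax_time <- d$times[pos][which.max(d$conc[pos])]

  ols <- function(idx) {
    t <- d$times[idx]; ly <- log(d$conc[idx])
    n <- length(idx)
    fit <- stats::lm.fit(cbind(1, t), ly)
    slope <- fit$coefficients[2]
    sse <- sum(fit$residuals^2)
    sst <- sum((ly - mean(ly))^2)
    r2 <- if (sst > 0) 1 - sse / sst else 1
    list(slope = unname(slope), intercept = unname(fit$coefficients[1]),
         n = n, r2_adj = 1 - (1 - r2) * (n - 1) / (n - 2))
  }

  if (!is.null(window)) {
    if (length(window) != 2) stop_quantpk("window must be a length-2 time range (minutes)")
    idx <- pos[d$times[pos] >= window[1] & d$times[pos] <= window[2]]
    if (length(idx) < 3) stop_quantpk("explicit window holds fewer than 3 positive points")
    f <- ols(idx)
    if (f$slope >= 0) stop_quantpk("terminal phase is not declining over the chosen window")
    best <- f; best_idx <- idx
  } else {
    elig <- pos[d$times[pos] > tmax_time]
    if (length(elig) < 3)
      stop_quantpk("need at least 3 positive concentrations after Tmax to fit lambda_z, got ",
                   length(elig))
    best <- NULL; best_idx <- NULL
    for (k in 3:length(elig)) {              # last k eligible points
      idx <- elig[(length(elig) - k + 1):length(elig)]
      f <- ols(idx)
      if (f$slope >= 0) next
      if (is.null(best) ||
          f$r2_adj > best$r2_adj + 1e-10 ||
          (abs(f$r2_adj - best$r2_adj) <= 1e-10 && f$n > best$n)) {
        best <- f; best_idx <- idx
      }
    }
    if (is.null(best))
      stop_quantpk("no declining terminal window found (flat or rising tail)")
  }
  list(lambda_z = -best$slope, intercept = best$intercept,
       window = d$times[best_idx], n_points = best$n, r2_adj = best$r2_adj)
}

#' Trapezoidal AUC and AUMC over a sampled curve
#'
#' Piecewise trapezoidal integration of the concentration curve and of its
#' first moment `t * C(t)` over the supplied grid. `"linear"` uses the linear
#' trapezoid everywhere; `"linear_up_log_down"` integrates declining segments
#' with both endpoints positive under a mono-exponential assumption (exact
#' for exponential decay) and everything else linearly.
#'
#' @param times sampling times (minutes), strictly increasing, length >= 2.
#' @param conc concentrations (any concentration unit), non-negative.
#' @param method `"linear"` or `"linear_up_log_down"`.
#' @return list with `auc` (time x conc units) and `aumc` (time^2 x conc).
#' @export
auc_trapezoid <- function(times, conc, method = c("linear", "linear_up_log_down")) {
  method <- match.arg(method)
  if (length(times) != length(conc)) stop_quantpk("times and conc lengths differ")
  if (length(times) < 2) stop_quantpk("at least 2 points are required")
  if (any(diff(times) <= 0)) stop_quantpk("times must be strictly increasing")
  if (all(conc == 0)) stop_quantpk("all-zero profile has no area")
  auc <- aumc <- 0
  for (i in seq_len(length(times) - 1)) {
    t1 <- times[i]; t2 <- times[i + 1]
    c1 <- conc[i]; c2 <- conc[i + 1]
    dt <- t2 - t1
    if (method == "linear_up_log_down" && c1 > c2 && c2 > 0) {
      k <- log(c1 / c2) / dt
      auc <- auc + (c1 - c2) / k
      aumc <- aumc + (t1 * c1 - t2 * c2) / k + (c1 - c2) / k^2
    } else {
      auc <- auc + (c1 + c2) / 2 * dt
      aumc <- aumc + (t1 * c1 + t2 * c2) / 2 * dt
    }
  }
  list(auc = auc, aumc = aumc)
}

#' Options for non-compartmental analysis
#'
#' @param auc_method trapezoidal rule passed to [auc_trapezoid()]; the linear
#'   rule is the conservative default, `"linear_up_log_down"` is preferable
#'   for sparse schedules over steep decay.
#' @param iv_c0 for IV bolus profiles whose first sample is after t = 0,
#'   back-extrapolate C(0) log-linearly from the first two positive points
#'   and include (0, C0) in the integration (standard NCA practice).
#' @param extravascular_t0 for oral profiles starting after t = 0, prepend
#'   the point (0, 0) — nothing has been absorbed at the instant of dosing.
#' @param lambda_z_window optional explicit time window for [fit_lambda_z()].
#' @return list of options for [compute_nca()].
#' @export
nca_options <- function(auc_method = c("linear", "linear_up_log_down"),
                        iv_c0 = TRUE, extravascular_t0 = TRUE,
                        lambda_z_window = NULL) {
  list(auc_method = match.arg(auc_method), iv_c0 = iv_c0,
       extravascular_t0 = extravascular_t0, lambda_z_window = lambda_z_window)
}

#' Non-compartmental analysis of one concentration-time profile
#'
#' Computes the standard NCA parameter set: Cmax/Tmax read from the observed
#' points; lambda_z from [fit_lambda_z()]; AUC and AUMC to the last positive
#' observation by [auc_trapezoid()] and extrapolated to infinity as
#' `AUC_inf = AUC_last + C_last / lambda_z` and
#' `AUMC_inf = AUMC_last + C_last t_last / lambda_z + C_last / lambda_z^2`;
#' `MRT = AUMC_inf / AUC_inf`. For IV profiles clearance and volumes follow:
#' `CL = dose / AUC_inf` (reported in ml/min/kg), `Vz = CL / lambda_z` and
#' `Vss = CL x MRT` (l/kg). For oral profiles these are undefined without an
#' absolute-bioavailability correction and are returned as `NA` with a
#' reason. Internally everything runs in minutes and umol/l; reported units
#' follow pharmacokinetic convention (Cmax uM, Tmax and t1/2 hours, AUC
#' min.umol/l).
#'
#' @param profile a [conc_time_profile].
#' @param options see [nca_options()].
#' @return object of class `nca_result`.
#' @export
compute_nca <- function(profile, options = nca_options()) {
  d <- blq_preprocess(profile)
  if (sum(d$conc > 0) < 2)
    stop_quantpk("profile has fewer than 2 quantifiable points; NCA impossible")
  lz <- fit_lambda_z(profile, window = options$lambda_z_window)

  # observed extremes, in reported units
  imax <- which.max(d$conc)
  cmax_um <- conc_ngml_to_um(d$conc[imax], profile$mw)
  tmax_h <- d$times[imax] / 60

  ilast <- max(which(d$conc > 0))
  times <- d$times[seq_len(ilast)]
  cu <- conc_ngml_to_um(d$conc[seq_len(ilast)], profile$mw)

  if (times[1] > 0) {
    if (profile$route == "IV" && isTRUE(options$iv_c0)) {
      ip <- which(cu > 0)[1:2]
      s <- (log(cu[ip[2]]) - log(cu[ip[1]])) / (times[ip[2]] - times[ip[1]])
      c0 <- if (is.finite(s) && s < 0) exp(log(cu[ip[1]]) - s * times[ip[1]]) else cu[ip[1]]
      times <- c(0, times); cu <- c(c0, cu)
    } else if (profile$route == "PO" && isTRUE(options$extravascular_t0)) {
      times <- c(0, times); cu <- c(0, cu)
    }
  }

  area <- auc_trapezoid(times, cu, method = options$auc_method)
  clast <- cu[length(cu)]
  tlast <- times[length(times)]
  auc_inf <- area$auc + clast / lz$lambda_z
  aumc_inf <- area$aumc + clast * tlast / lz$lambda_z + clast / lz$lambda_z^2
  mrt <- aumc_inf / auc_inf

  if (profile$route == "IV") {
    dose_u <- dose_mgkg_to_umolkg(profile$dose, profile$mw)
    cl_lminkg <- dose_u / auc_inf            # umol/kg / (min.umol/l) = l/min/kg
    cl <- 1000 * cl_lminkg                   # ml/min/kg
    vz <- cl_lminkg / lz$lambda_z            # l/kg
    vss <- cl_lminkg * mrt                   # l/kg
    reason <- NA_character_
  } else {
    cl <- vz <- vss <- NA_real_
    reason <- "clearance and volumes require IV dosing (oral F unknown)"
  }

  structure(list(
    subject_id = profile$subject_id, route = profile$route,
    dose = profile$dose, mw = profile$mw,
    cmax = cmax_um, tmax = tmax_h,
    lambda_z = lz$lambda_z,
    apparent_t_half = log(2) / lz$lambda_z / 60,
    auc_last = area$auc, auc_inf = auc_inf,
    pct_extrapolated = 100 * (auc_inf - area$auc) / auc_inf,
    aumc_inf = aumc_inf, mrt = mrt,
    cl_total = cl, vz = vz, vss = vss,
    disposition_reason = reason,
    lambda_z_window = lz$window, lambda_z_r2_adj = lz$r2_adj,
    auc_method = options$auc_method
  ), class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf("NCA: subject %s, %s %g mg/kg\n", x$subject_id, x$route, x$dose))
  cat(sprintf("  Cmax %.3g uM at Tmax %.2g h; t1/2 %.3g h (lambda_z %.4g /min, adj r2 %.4f)\n",
              x$cmax, x$tmax, x$apparent_t_half, x$lambda_z, x$lambda_z_r2_adj))
  cat(sprintf("  AUC_last %.4g, AUC_inf %.4g min.umol/l (%.1f%% extrapolated), MRT %.4g min\n",
              x$auc_last, x$auc_inf, x$pct_extrapolated, x$mrt))
  if (x$route == "IV")
    cat(sprintf("  CL %.3g ml/min/kg, Vz %.3g l/kg, Vss %.3g l/kg\n",
                x$cl_total, x$vz, x$vss))
  invisible(x)
}

#' @export
as.data.frame.nca_result <- function(x, ...) {
  data.frame(subject_id = x$subject_id, route = x$route, dose_mg_per_kg = x$dose,
             cmax_um = x$cmax, tmax_h = x$tmax,
             t_half_h = x$apparent_t_half, lambda_z_per_min = x$lambda_z,
             auc_last_min_umol_l = x$auc_last, auc_inf_min_umol_l = x$auc_inf,
             pct_extrapolated = x$pct_extrapolated, mrt_min = x$mrt,
             cl_ml_min_kg = x$cl_total, vz_l_kg = x$vz, vss_l_kg = x$vss)
}

#' Dose-normalized oral bioavailability
#'
#' `F (%) = 100 * (AUC_po / dose_po) / (AUC_iv / dose_iv)`. The ratio is
#' invariant under any consistent change of AUC units or dose units applied
#' to both routes, so AUCs may be supplied in min.umol/l or ng.min/ml and
#' doses in mg/kg or umol/kg, as long as each pair matches.
#'
#' @param auc_oral,auc_iv AUC(0-inf) for the oral and IV arms, same units.
#' @param dose_oral,dose_iv administered doses, same units.
#' @return list of class `bioavailability_result` with `f_pct` and the
#'   inputs.
#' @export
#' @examples
#' bioavailability(auc_oral = 287, dose_oral = 40, auc_iv = 222, dose_iv = 5)
bioavailability <- function(auc_oral, dose_oral, auc_iv, dose_iv) {
  vals <- c(auc_oral, dose_oral, auc_iv, dose_iv)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop_quantpk("all AUCs and doses must be positive")
  structure(list(f_pct = 100 * (auc_oral / dose_oral) / (auc_iv / dose_iv),
                 auc_oral = auc_oral, auc_iv = auc_iv,
                 dose_oral = dose_oral, dose_iv = dose_iv),
            class = "bioavailability_result")
}

#' @export
print.bioavailability_result <- function(x, ...) {
  cat(sprintf("Oral bioavailability F = %.1f%% (AUC %.4g @ %g vs IV AUC %.4g @ %g)\n",
              x$f_pct, x$auc_oral, x$dose_oral, x$auc_iv, x$dose_iv))
  invisible(x)
}
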