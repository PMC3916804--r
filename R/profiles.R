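#' Blood concentration-time profile
#'
#' Container for one subject's (or one mean curve's) dosing information and
#' sampled blood concentrations. Concentrations below the assay's lower limit
#' of quantification may be stored as 0 (the "BLQ" convention used by the CSV
#' readers/writers); how they enter the analysis is decided by
#' [compute_nca()].
#'
#' @param subject_id identifier.
#' @param route `"PO"` (oral) or `"IV"` (intravenous bolus).
#' @param dose dose in mg/kg, positive.
#' @param mw molecular weight of the analyte in g/mol, positive.
#' @param times sampling times in minutes, strictly increasing, >= 0.
#' @param conc blood concentrations in ng/ml, non-negative, same length as
#'   `times`.
#' @param lloq assay lower limit of quantification in ng/ml.
#' @return object of class `conc_time_profile`.
#' @export
conc_time_profile <- function(subject_id, route = c("PO", "IV"), dose, mw,
                              times, conc, lloq = 0) {
  route <- match.arg(route)
  if (length(times) != length(conc))
    stop_quantpk("times and conc must have the same length")
  if (length(times) && any(diff(times) <= 0))
    stop_quantpk("times must be strictly increasing")
  if (any(times < 0)) stop_quantpk("times must be >= 0")
  if (any(conc < 0)) stop_quantpk("concentrations must be >= 0")
  if (dose <= 0) stop_quantpk("dose must be positive")
  if (mw <= 0) stop_quantpk("molecular weight must be positive")
  structure(list(subject_id = as.character(subject_id), route = route,
                 dose = dose, mw = mw, times = as.numeric(times),
                 conc = as.numeric(conc), lloq = lloq),
            class = "conc_time_profile")
}

#' @export
print.conc_time_profile <- function(x, ...) {
  cat(sprintf("Concentration-time profile '%s' (%s, %g mg/kg, MW %g)\n",
              x$subject_id, x$route, x$dose, x$mw))
  print(data.frame(time_min = x$times, conc_ng_per_ml = x$conc))
  invisible(x)
}

#' Unit conversions between mass and molar scales
#'
#' The assay reports ng/ml while pharmacokinetic tables are conventionally
#' molar: `umol/l = (ng/ml) / MW` and `umol/kg = 1000 * (mg/kg) / MW`.
#'
#' @param conc concentration in ng/ml.
#' @param dose dose in mg/kg.
#' @param mw molecular weight in g/mol, positive.
#' @return the converted quantity.
#' @export
conc_ngml_to_um <- function(conc, mw) {
  if (mw <= 0) stop_quantpk("molecular weight must be positive")
  conc / mw
}

#' @rdname conc_ngml_to_um
#' @export
dose_mgkg_to_umolkg <- function(dose, mw) {
  if (mw <= 0) stop_quantpk("molecular weight must be positive")
  1000 * dose / mw
}

#' Mean concentration-time profile of a dose group
#'
#' Arithmetic mean concentration at each nominal sampling time across animals
#' sharing a schedule, route, dose and analyte — the curve shown in a mean
#' blood concentration vs. time figure. Stored BLQ values (zeros) enter the
#' mean as zero.
#'
#' @param profiles list of [conc_time_profile] objects with identical time
#'   grids, route, dose and molecular weight.
#' @return a `conc_time_profile` whose `subject_id` records the group size,
#'   e.g. `"mean(n=5)"`.
#' @export
mean_profile <- function(profiles) {
  if (length(profiles) < 1) stop_quantpk("no profiles supplied")
  p1 <- profiles[[1]]
  for (p in profiles[-1]) {
    if (!isTRUE(all.equal(p$times, p1$times)))
      stop_quantpk("profiles do not share a sampling schedule")
    if (p$route != p1$route || p$dose != p1$dose || p$mw != p1$mw)
      stop_quantpk("profiles differ in route, dose or molecular weight")
  }
  cmat <- do.call(rbind, lapply(profiles, `[[`, "conc"))
  conc_time_profile(sprintf("mean(n=%d)", length(profiles)),
                    route = p1$route, dose = p1$dose, mw = p1$mw,
                    times = p1$times, conc = colMeans(cmat), lloq = p1$lloq)
}
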