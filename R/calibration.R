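#' Instrument response for a set of batch records
#'
#' @param records data frame of batch records (see [read_batch_csv()] for the
#'   column layout); needs `analyte_area` and, for the ratio basis, `is_area`.
#' @param response_basis `"area_ratio"` (analyte area / internal-standard
#'   area, the usual choice when an internal standard is spiked) or `"area"`
#'   (raw analyte peak area).
#' @return numeric vector of responses, one per record.
#' @export
calibration_response <- function(records, response_basis = c("area_ratio", "area")) {
  response_basis <- match.arg(response_basis)
  if (response_basis == "area") return(records$analyte_area)
  if (any(is.na(records$is_area)) || any(records$is_area <= 0))
    stop_quantpk("area_ratio basis requires a positive internal-standard area for every record")
  records$analyte_area / records$is_area
}

#' Fit a calibration curve to calibration standards
#'
#' Fits the concentration-response model used for back-calculation. The
#' default `"wagner"` model is quadratic in log-log space,
#' `ln(y) = a (ln x)^2 + b ln(x) + c`, fitted by ordinary least squares on
#' `(ln x, ln y)`; `"linear_loglog"` is the same with `a` fixed at zero
#' (a power law), and `"linear"` is an untransformed straight line
#' `y = c + b x`. The log-log models require strictly positive responses and
#' concentrations; fits whose predicted response is not strictly increasing
#' over the calibration range are rejected, because such a curve cannot be
#' inverted unambiguously.
#'
#' @param standards data frame of calibration-standard records with columns
#'   `nominal_conc` (ng/ml), `analyte_area` and (for the ratio basis)
#'   `is_area`. At least six distinct nominal concentrations are required.
#' @param model_kind `"wagner"`, `"linear_loglog"` or `"linear"`.
#' @inheritParams calibration_response
#' @param weights optional per-record regression weights; the presets
#'   `"1/x"` and `"1/x2"` weight by inverse (squared) nominal concentration.
#'   The default is unweighted, since the log transform already stabilises
#'   the multiplicative variance typical of peak areas.
#' @return an object of class `calibration_fit`: a list with `model_kind`,
#'   `response_basis`, coefficients `coeff_a`, `coeff_b`, `coeff_c`, range
#'   `lloq`/`uloq` (the smallest and largest standard concentrations),
#'   `r_squared` (coefficient of determination in the fitting space) and
#'   `n_points`.
#' @seealso [predict_response()], [back_calculate()], [evaluate_curve()]
#' @export
#' @examples
#' std <- data.frame(nominal_conc = c(3.91, 7.82, 15.6, 62.5, 250, 1000),
#'                   analyte_area = 10 * c(3.91, 7.82, 15.6, 62.5, 250, 1000))
#' fit <- fit_calibration(std, model_kind = "wagner", response_basis = "area")
#' back_calculate(fit, predict_response(fit, 100))
fit_calibration <- function(standards,
                            model_kind = c("wagner", "linear_loglog", "linear"),
                            response_basis = c("area_ratio", "area"),
                            weights = NULL) {
  model_kind <- match.arg(model_kind)
  response_basis <- match.arg(response_basis)
  x <- standards$nominal_conc
  if (is.null(x) || any(is.na(x)))
    stop_quantpk("every calibration standard needs a nominal concentration")
  y <- calibration_response(standards, response_basis)
  if (length(unique(x)) < 6)
    stop_quantpk("calibration requires at least 6 distinct nominal concentrations, got ",
                 length(unique(x)))
  if (any(x <= 0)) stop_quantpk("nominal concentrations must be positive")
  if (any(y <= 0)) stop_quantpk("responses must be positive")

  w <- if (is.character(weights)) {
    switch(weights, "1/x" = 1 / x, "1/x2" = 1 / x^2,
           stop_quantpk("unknown weight preset: ", weights))
  } else weights %||% rep(1, length(x))

  lloq <- min(x)
  uloq <- max(x)

  if (model_kind == "linear") {
    fit <- stats::lm(y ~ x, weights = w)
    cf <- stats::coef(fit)
    a <- 0; b <- unname(cf[["x"]]); cc <- unname(cf[["(Intercept)"]])
    fitted_v <- stats::fitted(fit); obs <- y
  } else {
    lx <- log(x); ly <- log(y)
    if (model_kind == "wagner") {
      fit <- stats::lm(ly ~ I(lx^2) + lx, weights = w)
      cf <- stats::coef(fit)
      a <- unname(cf[["I(lx^2)"]]); b <- unname(cf[["lx"]])
      cc <- unname(cf[["(Intercept)"]])
    } else {
      fit <- stats::lm(ly ~ lx, weights = w)
      cf <- stats::coef(fit)
      a <- 0; b <- unname(cf[["lx"]]); cc <- unname(cf[["(Intercept)"]])
    }
    fitted_v <- stats::fitted(fit); obs <- ly
  }

  # R^2 in the fitting space, computed directly so degenerate perfect fits
  # do not warn
  sse <- sum(w * (obs - fitted_v)^2)
  sst <- sum(w * (obs - stats::weighted.mean(obs, w))^2)
  r2 <- if (sst > 0) 1 - sse / sst else 1

  out <- structure(
    list(model_kind = model_kind, response_basis = response_basis,
         coeff_a = a, coeff_b = b, coeff_c = cc,
         lloq = lloq, uloq = uloq,
         r_squared = r2, n_points = length(y)),
    class = "calibration_fit")
  assert_monotone(out)
  out
}

# the fitted response must be strictly increasing in concentration over
# [lloq, uloq]; for the log-log models the log-space derivative 2a ln(x) + b
# is linear in ln(x), so checking both endpoints suffices
assert_monotone <- function(fit) {
  if (fit$model_kind == "linear") {
    if (fit$coeff_b <= 0)
      stop_quantpk("calibration curve is not strictly increasing (slope <= 0)")
    return(invisible(fit))
  }
  d <- 2 * fit$coeff_a * log(c(fit$lloq, fit$uloq)) + fit$coeff_b
  if (any(d <= 0))
    stop_quantpk("calibration curve is not strictly monotone increasing over [",
                 fit$lloq, ", ", fit$uloq, "] ng/ml (2a ln(x) + b <= 0); fit rejected")
  invisible(fit)
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("Calibration fit (%s, response = %s)\n", x$model_kind, x$response_basis))
  if (x$model_kind == "linear") {
    cat(sprintf("  y = %.6g + %.6g * x\n", x$coeff_c, x$coeff_b))
  } else {
    cat(sprintf("  ln(y) = %.6g (ln x)^2 + %.6g ln(x) + %.6g\n",
                x$coeff_a, x$coeff_b, x$coeff_c))
  }
  cat(sprintf("  range: %.4g - %.4g ng/ml, n = %d, r^2 = %.6f\n",
              x$lloq, x$uloq, x$n_points, x$r_squared))
  invisible(x)
}

#' Predicted instrument response at a concentration
#'
#' Forward evaluation of a [calibration_fit]: for the log-log models returns
#' `exp(a (ln conc)^2 + b ln(conc) + c)`.
#'
#' @param fit a `calibration_fit`.
#' @param conc concentration(s) in ng/ml, strictly positive.
#' @return predicted response(s) on the fit's response basis.
#' @export
predict_response <- function(fit, conc) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (any(conc <= 0)) stop_quantpk("concentration must be positive")
  if (fit$model_kind == "linear") return(fit$coeff_c + fit$coeff_b * conc)
  u <- log(conc)
  exp(fit$coeff_a * u^2 + fit$coeff_b * u + fit$coeff_c)
}

#' Back-calculate concentrations from instrument responses
#'
#' Inverts the calibration curve. For the quadratic log-log model this solves
#' `a u^2 + b u + (c - ln y) = 0` for `u = ln(conc)` and takes the root on
#' the strictly increasing branch (`2 a u + b > 0`), which is unique for any
#' fit accepted by [fit_calibration()]; when `|a|` is below `a_tol` the
#' linear log-log solution is used instead to avoid catastrophic
#' cancellation. Results outside `[lloq, uloq]` are flagged, not rejected,
#' because diluted samples legitimately read above the upper limit before
#' dilution correction.
#'
#' @inheritParams predict_response
#' @param response observed response(s), strictly positive, on the fit's
#'   response basis.
#' @param dilution_factor factor (>= 1) the sample was diluted by before
#'   extraction; the back-calculated concentration is multiplied by it.
#' @param quality if `TRUE`, return a data frame with columns `conc` and
#'   `out_of_range` (the range check is applied to the measured, pre-dilution
#'   concentration); otherwise a bare numeric vector.
#' @param a_tol threshold on `|a|` below which the quadratic is treated as
#'   linear in log space.
#' @return concentrations in ng/ml (vector or data frame, see `quality`).
#' @export
back_calculate <- function(fit, response, dilution_factor = 1,
                           quality = FALSE, a_tol = 1e-12) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (any(response <= 0)) stop_quantpk("response must be positive")
  if (any(dilution_factor < 1)) stop_quantpk("dilution_factor must be >= 1")

  if (fit$model_kind == "linear") {
    measured <- (response - fit$coeff_c) / fit$coeff_b
    if (any(measured <= 0))
      stop_quantpk("response below the curve intercept; concentration unresolvable")
  } else {
    ly <- log(response)
    a <- fit$coeff_a; b <- fit$coeff_b; cc <- fit$coeff_c
    if (abs(a) < a_tol) {
      u <- (ly - cc) / b
    } else {
      disc <- b^2 - 4 * a * (cc - ly)
      if (any(disc < 0))
        stop_quantpk("response not reachable by the calibration curve (negative discriminant)")
      u <- (-b + sqrt(disc)) / (2 * a)
    }
    measured <- exp(u)
  }
  conc <- measured * dilution_factor
  if (!quality) return(conc)
  data.frame(conc = conc,
             out_of_range = measured < fit$lloq | measured > fit$uloq)
}

#' Per-level statistics of back-calculated calibration standards
#'
#' Back-calculates every standard against the fit and summarises each nominal
#' level with [level_stats()] (mean, %Nom, %CV, %Bias, n), the layout of a
#' cumulative calibration-standards table.
#'
#' @inheritParams predict_response
#' @param standards data frame of standard records (`nominal_conc`,
#'   `analyte_area`, `is_area`, optionally `level_label`).
#' @return data frame with one row per nominal level, ordered by
#'   concentration.
#' @export
evaluate_curve <- function(fit, standards) {
  resp <- calibration_response(standards, fit$response_basis)
  conc <- back_calculate(fit, resp)
  noms <- sort(unique(standards$nominal_conc))
  rows <- lapply(noms, function(nm) {
    sel <- standards$nominal_conc == nm
    st <- level_stats(conc[sel], nm)
    lab <- if (!is.null(standards$level_label)) standards$level_label[sel][1] else NA_character_
    cbind(data.frame(level_label = lab, nominal_conc = nm), st)
  })
  do.call(rbind, rows)
}

#' Blank-interference (specificity) check
#'
#' Compares blank responses with the response at the lower limit of
#' quantification. For each blank lot the analyte area is expressed as a
#' fraction of the mean LLOQ analyte area, and the internal-standard area as
#' a fraction of the mean LLOQ internal-standard area. Default thresholds are
#' the regulatory convention: blank analyte response below 20% of the LLOQ
#' response, blank internal-standard response below 5% of the working IS
#' response.
#'
#' @param blanks data frame of blank records (`analyte_area`, `is_area`,
#'   `matrix_lot`).
#' @param lloq_records data frame of records at the LLOQ (`analyte_area`,
#'   `is_area`).
#' @param analyte_threshold,is_threshold pass thresholds on the fractions.
#' @param check_is apply the internal-standard channel check. Set `FALSE`
#'   for in-batch blanks, which are spiked with internal standard and so
#'   legitimately show a full IS response; keep `TRUE` for unspiked source
#'   blanks, where any IS-channel signal is interference.
#' @return data frame with one row per blank record: `matrix_lot`,
#'   `analyte_fraction`, `is_fraction`, `pass_analyte`, `pass_is`, `pass`.
#' @export
check_specificity <- function(blanks, lloq_records,
                              analyte_threshold = 0.20, is_threshold = 0.05,
                              check_is = TRUE) {
  if (nrow(blanks) < 1) stop_quantpk("at least one blank record is required")
  if (nrow(lloq_records) < 1) stop_quantpk("at least one LLOQ record is required")
  mean_lloq <- mean(lloq_records$analyte_area)
  if (!is.finite(mean_lloq) || mean_lloq <= 0)
    stop_quantpk("mean LLOQ analyte response is zero; specificity fractions undefined")
  is_vals <- lloq_records$is_area[!is.na(lloq_records$is_area)]
  mean_is <- if (length(is_vals)) mean(is_vals) else NA_real_

  fa <- blanks$analyte_area / mean_lloq
  fi <- if (!check_is || is.na(mean_is)) rep(NA_real_, nrow(blanks))
        else blanks$is_area / mean_is
  pa <- fa < analyte_threshold
  pi_ <- is.na(fi) | fi < is_threshold
  data.frame(matrix_lot = blanks$matrix_lot %||% rep(NA_character_, nrow(blanks)),
             analyte_fraction = fa, is_fraction = fi,
             pass_analyte = pa, pass_is = pi_, pass = pa & pi_)
}
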