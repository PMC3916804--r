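# shared fixture builders -- everything is generated in code, no stored data

# noise-free standard records from a known log-log quadratic curve
exact_standards <- function(a, b, c,
                            nominals = c(3.910, 7.821, 15.64, 31.28, 62.57,
                                         125.0, 250.0, 500.2, 1000),
                            reps = 2, is_area = 400000) {
  x <- rep(nominals, each = reps)
  u <- log(x)
  resp <- exp(a * u^2 + b * u + c)
  data.frame(sample_id = sprintf("std%02d", seq_along(x)), batch_id = "b1",
             role = "STD", level_label = sprintf("STD %.4g", x),
             nominal_conc = x, analyte_area = resp * is_area,
             is_area = is_area, matrix_lot = "l1",
             condition_tag = NA_character_, dilution_factor = 1)
}

# a calibration_fit that reproduces (a, b, c) exactly (noise-free refit)
exact_fit <- function(a, b, c, ...) {
  fit_calibration(exact_standards(a, b, c, ...),
                  model_kind = "wagner", response_basis = "area_ratio")
}

# random coefficient sets whose curve is strictly increasing on [lloq, uloq]
random_monotone_coefs <- function(n, lloq = 3.910, uloq = 1000) {
  lo <- log(lloq); hi <- log(uloq)
  b <- runif(n, 0.3, 1.5)
  # need 2 a u + b > 0 on [lo, hi]; bound a away from the violation edge
  a_min <- -0.95 * b / (2 * hi)
  a_max <- 0.3 * b / (2 * max(abs(lo), 1))
  data.frame(a = runif(n, a_min, a_max), b = b, c = runif(n, -8, 2))
}

# exact mono-exponential IV profile, concentrations in ng/ml
exp_profile <- function(c0_um = 100, ke = 0.005, mw = 504.85, dose = 5,
                        times = c(5, 30, 60, 180, 300, 420, 720, 1440),
                        lloq = 0, subject = "iv1") {
  conc_time_profile(subject, route = "IV", dose = dose, mw = mw,
                    times = times, conc = c0_um * exp(-ke * times) * mw,
                    lloq = lloq)
}
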