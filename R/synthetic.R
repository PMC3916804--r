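#' Ground truth for a synthetic MRM peak-area assay
#'
#' Bundles the generating parameters from which [make_batch()] and
#' [make_matrix_effect_set()] simulate peak-area batches: the generating
#' calibration curve `ln(y) = a (ln x)^2 + b ln(x) + c` (y in arbitrary
#' response units, x in ng/ml), multiplicative lognormal noise on analyte and
#' internal-standard areas, lognormal matrix-lot effects with a configurable
#' analyte/IS correlation (internal-standard normalization only cancels the
#' correlated part of lot-to-lot suppression), an extraction recovery applied
#' to analyte areas, and a small additive baseline on blanks.
#'
#' The defaults give peak areas of realistic magnitude for an MRM assay over
#' a 3.9-1000 ng/ml range (about 1e4 at 10 ng/ml) with mid-single-digit
#' percent noise, matching the precision range typical of validated LC-MS/MS
#' methods.
#'
#' @param coeff_a,coeff_b,coeff_c generating curve coefficients; the curve
#'   must be strictly increasing over the design range.
#' @param response_basis `"area_ratio"` or `"area"` (what downstream fits
#'   will use).
#' @param analyte_noise_cv,is_noise_cv multiplicative noise CVs in percent.
#' @param is_nominal_area mean internal-standard peak area.
#' @param matrix_lot_sigma lognormal sigma of per-lot suppression/enhancement
#'   factors.
#' @param lot_correlation correlation between analyte and IS log lot effects
#'   in `[-1, 1]`.
#' @param recovery_true extraction recovery applied to analyte areas, in
#'   (0, 1].
#' @param blank_baseline_area mean analyte area in blanks (0 for perfectly
#'   clean blanks).
#' @param seed default RNG seed for the generators.
#' @return list of class `assay_truth`.
#' @export
assay_truth <- function(coeff_a = -0.003, coeff_b = 1.0, coeff_c = 7.2,
                        response_basis = c("area_ratio", "area"),
                        analyte_noise_cv = 5, is_noise_cv = 3,
                        is_nominal_area = 420000,
                        matrix_lot_sigma = 0.05, lot_correlation = 0.8,
                        recovery_true = 0.7, blank_baseline_area = 0,
                        seed = 1L) {
  response_basis <- match.arg(response_basis)
  if (analyte_noise_cv < 0 || is_noise_cv < 0) stop_quantpk("noise CVs must be >= 0")
  if (recovery_true <= 0 || recovery_true > 1) stop_quantpk("recovery_true must be in (0, 1]")
  if (abs(lot_correlation) > 1) stop_quantpk("lot_correlation must be in [-1, 1]")
  structure(list(coeff_a = coeff_a, coeff_b = coeff_b, coeff_c = coeff_c,
                 response_basis = response_basis,
                 analyte_noise_cv = analyte_noise_cv, is_noise_cv = is_noise_cv,
                 is_nominal_area = is_nominal_area,
                 matrix_lot_sigma = matrix_lot_sigma,
                 lot_correlation = lot_correlation,
                 recovery_true = recovery_true,
                 blank_baseline_area = blank_baseline_area,
                 seed = as.integer(seed)),
            class = "assay_truth")
}

wagner_response <- function(truth, conc) {
  u <- log(conc)
  exp(truth$coeff_a * u^2 + truth$coeff_b * u + truth$coeff_c)
}

#' The standard validation batch design
#'
#' Nine calibration standards (3.910-1000 ng/ml) in duplicate, seven QC
#' levels (3.909-800.0 ng/ml) in six-fold, an optional six-fold dilution QC
#' at 1600 ng/ml (diluted 2x before extraction), six blanks, two double
#' blanks and three system performance verification samples.
#'
#' @param include_dilution include the 1600 ng/ml dilution QC level.
#' @return data frame with columns `role`, `level_label`, `nominal_conc`,
#'   `n`, `dilution_factor` — the `design` argument of [make_batch()].
#' @export
validation_batch_design <- function(include_dilution = TRUE) {
  std <- data.frame(
    role = "STD",
    level_label = paste("STD", LETTERS[2:10]),
    nominal_conc = c(3.910, 7.821, 15.64, 31.28, 62.57, 125.0, 250.0, 500.2, 1000),
    n = 2, dilution_factor = 1)
  qc <- data.frame(
    role = "QC",
    level_label = paste("QC", LETTERS[1:7]),
    nominal_conc = c(3.909, 10.01, 20.01, 60.03, 160.1, 400.2, 800.0),
    n = 6, dilution_factor = 1)
  extra <- data.frame(
    role = c("BLANK", "DOUBLE_BLANK", "SPVS"),
    level_label = c(NA, NA, "SPVS"),
    nominal_conc = c(NA, NA, 400.2),
    n = c(6, 2, 3), dilution_factor = 1)
  out <- rbind(std, qc)
  if (include_dilution)
    out <- rbind(out, data.frame(role = "QC", level_label = "QC H DIL",
                                 nominal_conc = 1600, n = 6, dilution_factor = 2))
  rbind(out, extra)
}

#' Simulate one batch of peak-area records
#'
#' Generates analyte and internal-standard peak areas for every sample in the
#' design: the analyte area is
#' `recovery_true x lot_effect x exp(a (ln x)^2 + b ln(x) + c) x lognormal noise`
#' at the measured (post-dilution) concentration `x`, the IS area is
#' `is_nominal_area x lot_effect_IS x lognormal noise`. One correlated pair
#' of lot effects is drawn per batch (one matrix lot per batch). Blanks get
#' the baseline analyte area only; double blanks additionally have no
#' internal standard. Identical seeds give identical batches.
#'
#' @param truth an [assay_truth].
#' @param design a design table as from [validation_batch_design()].
#' @param batch_id,matrix_lot identifiers stamped on the records.
#' @param seed RNG seed (defaults to the truth's).
#' @return data frame of batch records in the layout of [read_batch_csv()].
#' @export
make_batch <- function(truth, design = validation_batch_design(),
                       batch_id = "batch1", matrix_lot = "lot1",
                       seed = truth$seed) {
  stopifnot(inherits(truth, "assay_truth"))
  if (is.null(design) || nrow(design) == 0) stop_quantpk("empty batch design")
  with_seed(seed, {
    lots <- draw_lot_effects(1, truth)
    rows <- lapply(seq_len(nrow(design)), function(i) {
      d <- design[i, ]
      reps <- lapply(seq_len(d$n), function(r) {
        role <- d$role
        if (role %in% c("BLANK", "DOUBLE_BLANK")) {
          analyte <- truth$blank_baseline_area * rlnorm_cv(1, 20)
          isa <- if (role == "DOUBLE_BLANK") NA_real_
                 else truth$is_nominal_area * lots$f_is[1] * rlnorm_cv(1, truth$is_noise_cv)
          nominal <- NA_real_
        } else {
          x <- d$nominal_conc / d$dilution_factor
          analyte <- truth$recovery_true * lots$f_analyte[1] *
            wagner_response(truth, x) * rlnorm_cv(1, truth$analyte_noise_cv)
          isa <- truth$is_nominal_area * lots$f_is[1] * rlnorm_cv(1, truth$is_noise_cv)
          nominal <- d$nominal_conc
        }
        lab <- if (is.na(d$level_label)) d$role else d$level_label
        data.frame(sample_id = sprintf("%s_%s_%d", batch_id, gsub(" ", "", lab), r),
                   batch_id = batch_id, role = role,
                   level_label = d$level_label, nominal_conc = nominal,
                   analyte_area = analyte, is_area = isa,
                   matrix_lot = matrix_lot, condition_tag = NA_character_,
                   dilution_factor = d$dilution_factor)
      })
      do.call(rbind, reps)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

# correlated lognormal lot effects for analyte and internal standard
draw_lot_effects <- function(n, truth) {
  s <- truth$matrix_lot_sigma
  if (s <= 0) return(data.frame(f_analyte = rep(1, n), f_is = rep(1, n)))
  za <- stats::rnorm(n, 0, s)
  zi <- truth$lot_correlation * za +
    sqrt(1 - truth$lot_correlation^2) * stats::rnorm(n, 0, s)
  data.frame(f_analyte = exp(za), f_is = exp(zi))
}

#' Simulate a matrix-effect experiment
#'
#' Blank matrix from `n_lots` sources, post-extraction spiked at the given
#' levels, plus matrix-free (neat solution) replicates. Each lot carries a
#' correlated pair of lognormal suppression/enhancement factors on the
#' analyte and internal-standard responses; matrix-free samples have factor
#' one. Since both sample types are unextracted solutions, no extraction
#' recovery is applied to either. The generating per-lot IS-normalized matrix
#' factor (`analyte factor / IS factor`) is returned alongside the records.
#'
#' @param truth an [assay_truth].
#' @param n_lots number of matrix sources.
#' @param levels data frame with `level_label` and `nominal_conc` (ng/ml);
#'   default high 800.0 and low 10.01.
#' @param n_free matrix-free replicates per level.
#' @param seed RNG seed.
#' @return list with `with_matrix` and `without_matrix` record data frames
#'   (filter by `level_label` before calling [matrix_factor()]) and
#'   `truth_mf` (`matrix_lot`, `true_mf`).
#' @export
make_matrix_effect_set <- function(truth, n_lots = 10,
                                   levels = data.frame(
                                     level_label = c("High", "Low"),
                                     nominal_conc = c(800.0, 10.01)),
                                   n_free = 6, seed = truth$seed) {
  stopifnot(inherits(truth, "assay_truth"))
  if (n_lots < 1) stop_quantpk("n_lots must be >= 1")
  with_seed(seed, {
    lots <- draw_lot_effects(n_lots, truth)
    lot_ids <- sprintf("lot%02d", seq_len(n_lots))
    wm <- do.call(rbind, lapply(seq_len(nrow(levels)), function(i) {
      x <- levels$nominal_conc[i]
      data.frame(sample_id = sprintf("mf_%s_%s", lot_ids, levels$level_label[i]),
                 batch_id = "matrix_effect", role = "MATRIX_EFFECT",
                 level_label = levels$level_label[i], nominal_conc = x,
                 analyte_area = lots$f_analyte * wagner_response(truth, x) *
                   rlnorm_cv(n_lots, truth$analyte_noise_cv),
                 is_area = lots$f_is * truth$is_nominal_area *
                   rlnorm_cv(n_lots, truth$is_noise_cv),
                 matrix_lot = lot_ids, condition_tag = "with_matrix",
                 dilution_factor = 1)
    }))
    free <- do.call(rbind, lapply(seq_len(nrow(levels)), function(i) {
      x <- levels$nominal_conc[i]
      data.frame(sample_id = sprintf("neat_%02d_%s", seq_len(n_free),
                                     levels$level_label[i]),
                 batch_id = "matrix_effect", role = "MATRIX_EFFECT",
                 level_label = levels$level_label[i], nominal_conc = x,
                 analyte_area = wagner_response(truth, x) *
                   rlnorm_cv(n_free, truth$analyte_noise_cv),
                 is_area = truth$is_nominal_area *
                   rlnorm_cv(n_free, truth$is_noise_cv),
                 matrix_lot = NA_character_, condition_tag = "without_matrix",
                 dilution_factor = 1)
    }))
    rownames(wm) <- rownames(free) <- NULL
    list(with_matrix = wm, without_matrix = free,
         truth_mf = data.frame(matrix_lot = lot_ids,
                               true_mf = lots$f_analyte / lots$f_is))
  })
}

#' Ground truth for a one-compartment blood PK simulation
#'
#' @param ka first-order absorption rate constant (1/min), used for oral
#'   dosing; must differ from `ke`.
#' @param ke first-order elimination rate constant (1/min).
#' @param v volume of distribution (l/kg).
#' @param f_true oral bioavailability fraction in (0, 1].
#' @param dose dose in mg/kg.
#' @param mw molecular weight (g/mol).
#' @param residual_cv multiplicative lognormal residual CV in percent.
#' @param sampling_times optional sampling schedule in minutes; when `NULL`
#'   the route default from [default_sampling_times()] is used.
#' @param lloq assay lower limit of quantification (ng/ml); simulated values
#'   below it are reported as BLQ (stored as 0).
#' @param seed default RNG seed.
#' @return list of class `pk_truth`.
#' @export
pk_truth <- function(ka = 0.02, ke = 0.004, v = 9, f_true = 0.25,
                     dose = 40, mw = 504.85, residual_cv = 15,
                     sampling_times = NULL, lloq = 3.910, seed = 1L) {
  if (ka <= 0 || ke <= 0) stop_quantpk("rate constants must be positive")
  if (v <= 0) stop_quantpk("volume must be positive")
  if (f_true <= 0 || f_true > 1) stop_quantpk("f_true must be in (0, 1]")
  if (residual_cv < 0) stop_quantpk("residual_cv must be >= 0")
  structure(list(model = "one_compartment", ka = ka, ke = ke, v = v,
                 f_true = f_true, dose = dose, mw = mw,
                 residual_cv = residual_cv, sampling_times = sampling_times,
                 lloq = lloq, seed = as.integer(seed)),
            class = "pk_truth")
}

#' Default blood-sampling schedules
#'
#' First sample 5 minutes after an IV bolus or 10 minutes after an oral dose
#' (no t = 0 sample is drawn), then 0.5, 1, 3, 5, 7, 12 and 24 hours.
#'
#' @param route `"PO"` or `"IV"`.
#' @return sampling times in minutes.
#' @export
default_sampling_times <- function(route = c("PO", "IV")) {
  route <- match.arg(route)
  c(if (route == "IV") 5 else 10, 30, 60, 180, 300, 420, 720, 1440)
}

# closed-form one-compartment blood concentration in umol/l
one_compartment_conc <- function(truth, route, dose, times) {
  d_u <- dose_mgkg_to_umolkg(dose, truth$mw)
  if (route == "IV") return(d_u / truth$v * exp(-truth$ke * times))
  if (truth$ka == truth$ke)
    stop_quantpk("the oral closed form is degenerate when ka = ke")
  truth$f_true * d_u * truth$ka / (truth$v * (truth$ka - truth$ke)) *
    (exp(-truth$ke * times) - exp(-truth$ka * times))
}

sim_profile_impl <- function(truth, route, dose, subject_id) {
  times <- truth$sampling_times %||% default_sampling_times(route)
  cu <- one_compartment_conc(truth, route, dose, times)
  ng <- cu * truth$mw * rlnorm_cv(length(times), truth$residual_cv)
  ng[ng < truth$lloq] <- 0                 # reported as BLQ
  conc_time_profile(subject_id, route = route, dose = dose, mw = truth$mw,
                    times = times, conc = ng, lloq = truth$lloq)
}

#' Simulate one blood concentration-time profile
#'
#' One-compartment kinetics: IV bolus `C(t) = (D/V) e^(-ke t)` or first-order
#' oral absorption
#' `C(t) = F D ka / (V (ka - ke)) (e^(-ke t) - e^(-ka t))`, with the dose in
#' umol/kg so concentrations come out in umol/l, converted to ng/ml, then
#' perturbed by multiplicative lognormal residuals and censored at the LLOQ
#' (BLQ values stored as 0).
#'
#' @param truth a [pk_truth].
#' @param route `"PO"` or `"IV"`.
#' @param dose dose in mg/kg (defaults to the truth's).
#' @param subject_id identifier.
#' @param seed RNG seed.
#' @return a [conc_time_profile].
#' @export
simulate_profile <- function(truth, route = c("PO", "IV"), dose = truth$dose,
                             subject_id = "sim1", seed = truth$seed) {
  stopifnot(inherits(truth, "pk_truth"))
  route <- match.arg(route)
  with_seed(seed, sim_profile_impl(truth, route, dose, subject_id))
}

#' Simulate a four-arm bioavailability study
#'
#' `n_animals` one-compartment profiles per arm for oral arms at
#' `doses_po` and IV arms at `doses_iv` (defaults 40/20 mg/kg PO and
#' 5/2.5 mg/kg IV, n = 5), all sharing the truth's rate constants, volume,
#' bioavailability and molecular weight. Oral arms use the oral sampling
#' schedule (first sample 10 min), IV arms the IV schedule (first sample
#' 5 min), unless the truth fixes its own.
#'
#' @param truth a [pk_truth].
#' @param n_animals animals per arm.
#' @param doses_po,doses_iv dose levels per route in mg/kg.
#' @param seed RNG seed.
#' @return list of class `pk_study` with `arms` (each: `route`, `dose`,
#'   `profiles`) and the generating `truth`.
#' @export
simulate_study <- function(truth, n_animals = 5, doses_po = c(40, 20),
                           doses_iv = c(5, 2.5), seed = truth$seed) {
  stopifnot(inherits(truth, "pk_truth"))
  with_seed(seed, {
    arms <- list()
    for (route in c("PO", "IV")) {
      doses <- if (route == "PO") doses_po else doses_iv
      for (dose in doses) {
        profiles <- lapply(seq_len(n_animals), function(i)
          sim_profile_impl(truth, route, dose,
                           sprintf("%s%g_animal%d", route, dose, i)))
        arms[[sprintf("%s_%g", route, dose)]] <-
          list(route = route, dose = dose, profiles = profiles)
      }
    }
    structure(list(arms = arms, truth = truth), class = "pk_study")
  })
}
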