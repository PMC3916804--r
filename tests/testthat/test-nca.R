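test_that("mass-to-molar conversions are definitional", {
  expect_equal(conc_ngml_to_um(504.85, 504.85), 1)
  expect_equal(conc_ngml_to_um(0, 504.85), 0)
  expect_equal(dose_mgkg_to_umolkg(5, 504.85), 5000 / 504.85)
  expect_error(conc_ngml_to_um(1, 0), "positive")
})

test_that("lambda_z is exact on mono-exponential data and ignores a BLQ tail", {
  p <- exp_profile(c0_um = 100, ke = 0.005)
  lz <- fit_lambda_z(p)
  expect_equal(lz$lambda_z, 0.005, tolerance = 1e-10)
  expect_equal(lz$r2_adj, 1, tolerance = 1e-12)
  expect_equal(lz$n_points, 7L)   # ties in adjusted r2 go to the longer window

  # append a censored sample after the last positive point: identical slope
  p_blq <- conc_time_profile("iv2", "IV", 5, 504.85,
                             times = c(p$times, 2880),
                             conc = c(p$conc, 0), lloq = 3.910)
  expect_equal(fit_lambda_z(p_blq)$lambda_z, lz$lambda_z, tolerance = 1e-12)
})

test_that("automatic window selection matches an exhaustive brute-force search", {
  # noisy bi-exponential disposition: steep distribution phase, then terminal
  set.seed(31)
  times <- c(5, 15, 30, 60, 120, 240, 360, 480, 720, 1080, 1440)
  conc <- (80 * exp(-0.03 * times) + 20 * exp(-0.003 * times)) *
    exp(rnorm(length(times), 0, 0.05))
  p <- conc_time_profile("bi1", "IV", 5, 500, times = times, conc = conc)
  got <- fit_lambda_z(p)

  # oracle: refit every admissible suffix window independently with lm()
  tmax_t <- times[which.max(conc)]
  elig <- which(times > tmax_t)
  best <- NULL
  for (k in 3:length(elig)) {
    idx <- elig[(length(elig) - k + 1):length(elig)]
    fit <- lm(log(conc[idx]) ~ times[idx])
    if (coef(fit)[2] >= 0) next
    r2 <- summary(fit)$r.squared
    r2a <- 1 - (1 - r2) * (k - 1) / (k - 2)
    if (is.null(best) || r2a > best$r2a + 1e-10 ||
        (abs(r2a - best$r2a) <= 1e-10 && k > best$k))
      best <- list(slope = unname(coef(fit)[2]), r2a = r2a, k = k, idx = idx)
  }
  expect_equal(got$lambda_z, -best$slope, tolerance = 1e-10)
  expect_equal(got$n_points, best$k)
  expect_equal(got$window, times[best$idx])
})

test_that("lambda_z degenerate inputs raise informative errors", {
  p1 <- conc_time_profile("s", "IV", 5, 500, times = c(10, 20), conc = c(5, 0),
                          lloq = 1)
  expect_error(fit_lambda_z(p1), "quantifiable|3 positive")
  rising <- conc_time_profile("s", "IV", 5, 500, times = c(10, 60, 120, 240),
                              conc = c(10, 1, 2, 3))
  expect_error(fit_lambda_z(rising), "declining|rising")
})

test_that("trapezoidal integration is exact on simple shapes and near-exact densely", {
  expect_equal(auc_trapezoid(c(0, 10), c(10, 10))$auc, 100)
  expect_equal(auc_trapezoid(c(0, 10, 20), c(0, 10, 0))$auc, 100)

  t <- 0:1440
  c_exp <- 10 * exp(-0.005 * t)
  closed <- (10 / 0.005) * (1 - exp(-7.2))
  expect_equal(auc_trapezoid(t, c_exp)$auc, closed, tolerance = 5e-4)
  # the log-down rule is exact on exponential decay
  expect_equal(auc_trapezoid(c(0, 100, 400, 1440), 10 * exp(-0.005 * c(0, 100, 400, 1440)),
                             method = "linear_up_log_down")$auc,
               closed, tolerance = 1e-12)
  expect_error(auc_trapezoid(c(0, 10), c(0, 0)), "all-zero")
})

test_that("AUC is additive over interior grid points (property)", {
  withr::local_seed(32)
  for (m in c("linear", "linear_up_log_down")) {
    t <- sort(runif(9, 0, 1000))
    conc <- rlnorm(9, 1, 0.8)
    k <- 5
    whole <- auc_trapezoid(t, conc, method = m)
    left <- auc_trapezoid(t[1:k], conc[1:k], method = m)
    right <- auc_trapezoid(t[k:9], conc[k:9], method = m)
    expect_equal(whole$auc, left$auc + right$auc, tolerance = 1e-12)
    expect_equal(whole$aumc, left$aumc + right$aumc, tolerance = 1e-12)
  }
})

test_that("NCA recovers one-compartment IV parameters: dense to 0.1%, sparse schedule to 2%", {
  mw <- 504.85; ke <- 0.005; v <- 9
  dose <- 5
  c0 <- dose_mgkg_to_umolkg(dose, mw) / v
  cl_true <- 1000 * ke * v                       # ml/min/kg

  dense <- conc_time_profile("dense", "IV", dose, mw, times = 0:1440,
                             conc = c0 * exp(-0.005 * (0:1440)) * mw)
  r <- compute_nca(dense)
  expect_equal(r$lambda_z, ke, tolerance = 1e-6)
  expect_equal(r$cl_total, cl_true, tolerance = 1e-3)
  expect_equal(r$vz, v, tolerance = 1e-3)
  expect_equal(r$vss, v, tolerance = 1e-3)
  expect_equal(r$apparent_t_half, log(2) / ke / 60, tolerance = 1e-6)

  sparse <- exp_profile(c0_um = c0, ke = ke, mw = mw, dose = dose)
  rs <- compute_nca(sparse, nca_options(auc_method = "linear_up_log_down"))
  expect_equal(rs$lambda_z, ke, tolerance = 1e-8)
  expect_equal(rs$cl_total, cl_true, tolerance = 0.02)
  expect_equal(rs$vz, v, tolerance = 0.02)
  expect_equal(rs$vss, v, tolerance = 0.02)
})

test_that("NCA output respects its own invariants and route rules", {
  p <- exp_profile()
  r <- compute_nca(p)
  expect_true(r$auc_inf >= r$auc_last)
  expect_true(r$auc_last > 0)
  expect_true(r$pct_extrapolated >= 0 && r$pct_extrapolated < 100)
  expect_equal(r$apparent_t_half, log(2) / r$lambda_z / 60, tolerance = 1e-12)

  po <- conc_time_profile("po1", "PO", 40, 504.85,
                          times = c(10, 30, 60, 180, 300, 420, 720, 1440),
                          conc = 1000 * (exp(-0.004 * c(10, 30, 60, 180, 300, 420, 720, 1440)) -
                                         exp(-0.02 * c(10, 30, 60, 180, 300, 420, 720, 1440))))
  rp <- compute_nca(po)
  expect_true(is.na(rp$cl_total) && is.na(rp$vz) && is.na(rp$vss))
  expect_match(rp$disposition_reason, "IV")

  single <- conc_time_profile("s1", "IV", 5, 500, times = c(5, 60, 120),
                              conc = c(100, 0, 0), lloq = 1)
  expect_error(compute_nca(single), "quantifiable")
})

test_that("trailing BLQ points do not change the NCA result", {
  p <- exp_profile(lloq = 3.910)
  p_tail <- conc_time_profile(p$subject_id, "IV", p$dose, p$mw,
                              times = c(p$times, 1800, 2880),
                              conc = c(p$conc, 0, 0), lloq = 3.910)
  r1 <- compute_nca(p)
  r2 <- compute_nca(p_tail)
  expect_equal(r1$auc_inf, r2$auc_inf, tolerance = 1e-12)
  expect_equal(r1$lambda_z, r2$lambda_z, tolerance = 1e-12)
  expect_equal(r1$cmax, r2$cmax)
})

test_that("extrapolated fraction shrinks as the sampling horizon extends", {
  mw <- 500
  horizons <- list(c(5, 30, 60, 180, 300, 420, 720),
                   c(5, 30, 60, 180, 300, 420, 720, 1440),
                   c(5, 30, 60, 180, 300, 420, 720, 1440, 2880))
  pext <- vapply(horizons, function(tt) {
    p <- conc_time_profile("h", "IV", 5, mw, times = tt,
                           conc = 100 * exp(-0.003 * tt))
    compute_nca(p)$pct_extrapolated
  }, numeric(1))
  expect_true(all(diff(pext) < 0))
})

test_that("bioavailability reproduces the dose-normalized AUC ratios", {
  expect_equal(round_half_up(bioavailability(287, 40, 222, 5)$f_pct, 1), 16.2)
  expect_equal(round_half_up(bioavailability(256, 20, 104, 2.5)$f_pct, 1), 30.8)
  expect_equal(round_half_up(bioavailability(541, 40, 221, 5)$f_pct, 1), 30.6)
  expect_equal(round_half_up(bioavailability(222, 20, 107, 2.5)$f_pct, 1), 25.9)
  expect_equal(bioavailability(100, 10, 50, 5)$f_pct, 100)
  expect_error(bioavailability(-1, 10, 50, 5), "positive")
})

test_that("bioavailability is invariant under consistent unit changes", {
  mw <- 504.85
  f1 <- bioavailability(287, 40, 222, 5)$f_pct
  # AUC in ng.min/ml instead of min.umol/l (multiply both by MW)
  f2 <- bioavailability(287 * mw, 40, 222 * mw, 5)$f_pct
  # doses in umol/kg instead of mg/kg
  f3 <- bioavailability(287, dose_mgkg_to_umolkg(40, mw),
                        222, dose_mgkg_to_umolkg(5, mw))$f_pct
  expect_equal(f1, f2, tolerance = 1e-12)
  expect_equal(f1, f3, tolerance = 1e-12)
})

test_that("mean profiles average columns and validate schedules", {
  mk <- function(conc, id) conc_time_profile(id, "PO", 40, 500,
                                             times = c(10, 30, 60), conc = conc)
  ps <- lapply(1:5, function(i) mk(c(5, 20, 10), paste0("a", i)))
  mp <- mean_profile(ps)
  expect_equal(mp$conc, c(5, 20, 10))
  expect_equal(mp$subject_id, "mean(n=5)")

  mp2 <- mean_profile(list(mk(c(0, 10, 4), "x"), mk(c(10, 0, 6), "y")))
  expect_equal(mp2$conc, c(5, 5, 5))

  withr::local_seed(33)
  ps3 <- lapply(1:5, function(i) mk(rlnorm(3, 2, 0.4), paste0("n", i)))
  mp3 <- mean_profile(ps3)
  oracle <- colMeans(do.call(rbind, lapply(ps3, `[[`, "conc")))
  expect_equal(mp3$conc, unname(oracle), tolerance = 1e-12)

  bad <- conc_time_profile("z", "PO", 40, 500, times = c(10, 30, 90), conc = c(1, 2, 3))
  expect_error(mean_profile(c(ps, list(bad))), "schedule")
})
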