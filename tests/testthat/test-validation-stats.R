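test_that("level_stats reproduces accuracy cells derivable from printed means", {
  # a pair symmetric about the target mean has exactly that mean
  around <- function(m, d = 0.1) c(m - d, m + d)
  qc_e <- level_stats(around(177.5), nominal = 160.1)
  expect_equal(round_half_up(qc_e$pct_nom, 1), 110.9)
  expect_equal(round_half_up(qc_e$pct_bias, 1), 10.9)
  qc_a <- level_stats(around(3.815, 0.01), nominal = 3.909)
  expect_equal(round_half_up(qc_a$pct_nom, 1), 97.6)
  expect_equal(round_half_up(qc_a$pct_bias, 1), -2.4)
})

test_that("level_stats on a constant vector gives perfect accuracy and zero CV", {
  st <- level_stats(c(50, 50, 50), nominal = 50)
  expect_equal(st$pct_nom, 100)
  expect_equal(st$pct_cv, 0)
  expect_equal(st$pct_bias, 0)
  expect_equal(st$n, 3L)
})

test_that("level_stats guards its inputs and defines %CV only for n >= 2", {
  expect_error(level_stats(numeric(0), 10), "at least one")
  expect_error(level_stats(c(1, 2), -1), "positive")
  expect_true(is.na(level_stats(5, 10)$pct_cv))
})

test_that("pct_nom - pct_bias = 100 for arbitrary inputs (property)", {
  withr::local_seed(11)
  for (i in 1:50) {
    st <- level_stats(rlnorm(sample(1:8, 1), 3, 1), nominal = rlnorm(1, 2, 1))
    expect_equal(st$pct_nom - st$pct_bias, 100, tolerance = 1e-12)
  }
})

test_that("statistics are permutation-invariant and scale-invariant", {
  withr::local_seed(12)
  v <- rlnorm(12, 4, 0.3)
  st1 <- level_stats(v, 60)
  st2 <- level_stats(sample(v), 60)
  expect_equal(st1, st2)

  ext <- data.frame(level_label = "L", nominal_conc = 10, analyte_area = rlnorm(6, 9, 0.1))
  ref <- data.frame(level_label = "L", nominal_conc = 10, analyte_area = rlnorm(6, 9.3, 0.1))
  r1 <- absolute_recovery(ext, ref)
  ext2 <- ext; ref2 <- ref
  ext2$analyte_area <- ext2$analyte_area * 7.3
  ref2$analyte_area <- ref2$analyte_area * 7.3
  r2 <- absolute_recovery(ext2, ref2)
  expect_equal(r1$recovery_pct, r2$recovery_pct, tolerance = 1e-12)
  expect_equal(r1$pct_cv, r2$pct_cv, tolerance = 1e-12)

  wm <- data.frame(matrix_lot = letters[1:6], analyte_area = rlnorm(6, 10, 0.1),
                   is_area = rlnorm(6, 12, 0.1))
  free <- data.frame(analyte_area = rlnorm(6, 10, 0.05), is_area = rlnorm(6, 12, 0.05))
  m1 <- matrix_factor(wm, free)
  wm2 <- wm; wm2$analyte_area <- wm2$analyte_area * 3; wm2$is_area <- wm2$is_area * 3
  m2 <- matrix_factor(wm2, free)
  expect_equal(m1$per_lot$is_mf, m2$per_lot$is_mf, tolerance = 1e-12)
  expect_equal(m1$pct_cv_mf, m2$pct_cv_mf, tolerance = 1e-12)
})

test_that("inter-batch pooling matches a concatenate-and-recompute oracle", {
  withr::local_seed(13)
  levels <- data.frame(level_label = c("QC A", "QC E", "QC G"),
                       nominal_conc = c(3.909, 160.1, 800.0))
  qc <- do.call(rbind, lapply(c("b1", "b2", "b3"), function(b) {
    do.call(rbind, lapply(seq_len(nrow(levels)), function(i) {
      data.frame(batch_id = b, level_label = levels$level_label[i],
                 nominal_conc = levels$nominal_conc[i],
                 conc = levels$nominal_conc[i] * rlnorm(6, 0, 0.06))
    }))
  }))
  res <- batch_and_run_statistics(qc)
  expect_equal(nrow(res$intra), 9L)
  expect_equal(res$inter$n, rep(18L, 3))
  for (i in seq_len(nrow(levels))) {
    all_vals <- qc$conc[qc$level_label == levels$level_label[i]]
    oracle <- level_stats(all_vals, levels$nominal_conc[i])
    got <- res$inter[res$inter$level_label == levels$level_label[i], ]
    expect_equal(got$mean, oracle$mean, tolerance = 1e-12)
    expect_equal(got$pct_cv, oracle$pct_cv, tolerance = 1e-12)
    expect_equal(got$pct_bias, oracle$pct_bias, tolerance = 1e-12)
  }
  # a pooled mean engineered at 10.12 against nominal 10.01 -> %Nom 101.1
  eng <- data.frame(batch_id = rep(c("b1", "b2"), each = 3), level_label = "QC B",
                    nominal_conc = 10.01,
                    conc = 10.12 + c(-0.3, 0.1, 0.2, -0.2, 0.3, -0.1))
  got <- batch_and_run_statistics(eng)$inter
  expect_equal(round_half_up(got$pct_nom, 1), 101.1)
})

test_that("zero-noise batches pool to n = 18 with zero CV, and missing levels are absent not fatal", {
  qc <- expand.grid(batch_id = c("b1", "b2", "b3"), rep = 1:6,
                    level_label = c("QC B", "QC G"), stringsAsFactors = FALSE)
  qc$nominal_conc <- ifelse(qc$level_label == "QC B", 10.01, 800)
  qc$conc <- qc$nominal_conc
  res <- batch_and_run_statistics(qc)
  expect_equal(res$inter$n, c(18L, 18L))
  expect_equal(res$inter$pct_cv, c(0, 0))
  expect_true(all(res$inter$pass))

  qc_missing <- qc[!(qc$batch_id == "b2" & qc$level_label == "QC G"), ]
  res2 <- batch_and_run_statistics(qc_missing)
  expect_equal(nrow(res2$intra), 5L)
  expect_equal(res2$inter$n[res2$inter$level_label == "QC G"], 12L)
})

test_that("absolute recovery reproduces the printed response-factor ratios", {
  two <- function(m) c(m - 1, m + 1)
  ext <- data.frame(level_label = c("High", "High", "Medium", "Medium", "ISTD", "ISTD"),
                    nominal_conc = c(800, 800, 160.1, 160.1, 100, 100),
                    analyte_area = c(two(825850), two(169317), two(418683)))
  ref <- data.frame(level_label = ext$level_label, nominal_conc = ext$nominal_conc,
                    analyte_area = c(two(1120664), two(260280), two(543089)))
  rec <- absolute_recovery(ext, ref)
  expect_equal(round_half_up(rec$recovery_pct[rec$level_label == "High"], 1), 73.7)
  expect_equal(round_half_up(rec$recovery_pct[rec$level_label == "Medium"], 1), 65.1)
  expect_equal(round_half_up(rec$recovery_pct[rec$level_label == "ISTD"], 1), 77.1)

  same <- absolute_recovery(ext, ext)
  expect_equal(same$recovery_pct, rep(100, 3), tolerance = 1e-12)
  bad <- ref; bad$analyte_area <- 0
  expect_error(absolute_recovery(ext, bad), "zero reference")
})

test_that("matrix factors cancel co-suppression and match a direct recomputation", {
  free <- data.frame(analyte_area = rep(1000, 4), is_area = rep(5000, 4))
  same <- data.frame(matrix_lot = c("a", "b"), analyte_area = 1000, is_area = 5000)
  r <- matrix_factor(same, free)
  expect_equal(r$per_lot$is_mf, c(1, 1))
  expect_equal(r$pct_cv_mf, 0)
  expect_true(r$pass)
  expect_equal(r$interpretation, "none")

  co <- data.frame(matrix_lot = "a", analyte_area = 800, is_area = 4000)
  expect_equal(matrix_factor(co, free)$per_lot$is_mf, 1, tolerance = 1e-12)

  withr::local_seed(14)
  wm <- data.frame(matrix_lot = sprintf("l%02d", 1:10),
                   analyte_area = 1000 * exp(rnorm(10, 0, 0.1)),
                   is_area = 5000 * exp(rnorm(10, 0, 0.1)))
  res <- matrix_factor(wm, free)
  ratios <- wm$analyte_area / wm$is_area
  mf_oracle <- ratios / mean(free$analyte_area / free$is_area)
  expect_equal(res$per_lot$is_mf, mf_oracle, tolerance = 1e-12)
  expect_equal(res$pct_cv_mf, 100 * sd(mf_oracle) / mean(mf_oracle), tolerance = 1e-12)
  expect_identical(res$pass, res$pct_cv_mf <= 15)
})

test_that("stability modes reproduce printed panel values and pass logic", {
  two <- function(m, d = 1) c(m - d, m + d)
  stock <- stability_assessment(two(813083, 100), mode = "pct_reference",
                                reference = two(760700, 100), condition = "stock_rt")
  expect_equal(round_half_up(stock$value, 1), 106.9)
  expect_true(stock$pass)

  ft <- stability_assessment(two(10.87, 0.05), mode = "pct_bias_vs_nominal",
                             nominal = 10.01, condition = "freeze_thaw")
  expect_equal(round_half_up(ft$value, 1), 8.6)
  expect_true(ft$pass)

  v <- c(9.8, 10.1, 10.3)
  same <- stability_assessment(v, mode = "pct_reference", reference = v)
  expect_equal(same$value, 100)
  diffm <- stability_assessment(v, mode = "pct_difference_vs_reference_set",
                                reference = v)
  expect_equal(diffm$value, 0)
  expect_true(diffm$pass)

  drifted <- stability_assessment(v * 0.80, mode = "pct_difference_vs_reference_set",
                                  reference = v)
  expect_false(drifted$pass)
  expect_error(stability_assessment(v, mode = "pct_reference"), "reference")
  expect_error(stability_assessment(v, mode = "pct_bias_vs_nominal"), "nominal")
})

test_that("cross-matrix validation flags the breach without failing hard", {
  two <- function(m, d) c(m - d, m + d)
  rec <- data.frame(
    level_label = rep(c("High", "Medium", "Low", "LLOQ"), each = 2),
    nominal_conc = rep(c(800.0, 160.0, 10.00, 3.906), each = 2),
    conc = c(two(899.3, 5), two(185.7, 2), two(10.66, 0.1), two(3.946, 0.05)))
  res <- cross_validate(rec)
  per <- res$per_level
  expect_equal(round_half_up(per$pct_bias[per$nominal_conc == 800], 1), 12.4)
  expect_true(per$pass[per$nominal_conc == 800])
  expect_equal(round_half_up(per$pct_bias[per$nominal_conc == 160], 1), 16.1)
  expect_false(per$pass[per$nominal_conc == 160])
  expect_false(res$pass)

  ident <- rec; ident$conc <- ident$nominal_conc
  res2 <- cross_validate(ident)
  expect_equal(res2$per_level$pct_bias, rep(0, 4))
  expect_true(res2$pass)
})

test_that("every pass decision re-evaluates from the reported numbers", {
  withr::local_seed(15)
  qc <- data.frame(batch_id = "b1", level_label = rep(c("A", "B"), each = 6),
                   nominal_conc = rep(c(3.909, 800), each = 6),
                   conc = c(3.909 * rlnorm(6, 0, 0.12), 800 * rlnorm(6, 0, 0.05)))
  inter <- batch_and_run_statistics(qc)$inter
  expect_identical(inter$pass,
                   abs(inter$pct_bias) <= inter$limit & inter$pct_cv <= inter$limit)
})
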