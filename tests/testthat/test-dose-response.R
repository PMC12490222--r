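test_that("cell-count outlier filtering is one-sided at 4 control SDs", {
  controls <- make_summary(rep("DMSO", 3), NA, NA,
                           n_total = c(8900, 9000, 9100),
                           n_viable = c(8000, 8000, 8000),
                           n_viable_blast = c(4800, 4800, 4800))
  treated <- make_summary(rep("drugA", 3), rep(1e-6, 3), 1:3,
                          n_total = c(9500, 9300, 8000),
                          n_viable = rep(7000, 3),
                          n_viable_blast = rep(4000, 3))
  kept <- filter_cellcount_outliers(treated, controls)
  # control mean 9000, SD 100 -> cut 9400: 9500 removed, 9300 and 8000 kept
  expect_setequal(kept$n_total, c(9300, 8000))
  expect_equal(attr(kept, "removed")$n_total, 9500)
})

test_that("equal control counts remove nothing and few controls error", {
  controls <- make_summary(rep("DMSO", 3), NA, NA, rep(9000, 3),
                           rep(8000, 3), rep(4800, 3))
  treated <- make_summary("drugA", 1e-6, 1, 9000, 7000, 4000)
  expect_equal(nrow(filter_cellcount_outliers(treated, controls)), 1)
  expect_error(filter_cellcount_outliers(treated, controls[1, ]),
               "2 control wells")
})

test_that("relative blast fraction is the ratio to the control mean", {
  controls <- make_summary(rep("DMSO", 2), NA, NA, c(100, 100), c(80, 80),
                           c(32, 32))  # fractions 0.4, 0.4
  treated <- make_summary(c("a", "b"), c(1e-6, 1e-6), c(1, 1),
                          c(100, 100), c(50, 60),
                          c(20, 12))  # fractions 0.4 and 0.2
  expect_equal(compute_rbf(treated, controls), c(1.0, 0.5))
  zero_ctrl <- make_summary(rep("DMSO", 2), NA, NA, c(100, 100), c(80, 80),
                            c(0, 0))
  expect_error(compute_rbf(treated, zero_ctrl), "unusable")
})

test_that("rule A drops rises above 1.5x the previous filtered average", {
  ser <- make_series(c(1e-7, 1e-7, 1e-6, 1e-6), c(0.5, 0.7, 0.95, 0.85))
  out <- filter_dose_response(ser)
  # previous average 0.6 -> cut 0.9: 0.95 dropped, 0.85 kept
  expect_setequal(out$value[out$concentration == 1e-6], 0.85)
  expect_equal(attr(out, "dropped")$value, 0.95)
  expect_equal(attr(out, "dropped")$reason,
               "rise-above-previous-concentration")
})

test_that("rule B drops concentrations with >50% replicate disagreement", {
  ser <- make_series(c(1e-7, 1e-7, 1e-6, 1e-6), c(0.2, 0.4, 0.3, 0.4))
  out <- filter_dose_response(ser)
  # |0.2 - 0.4| / 0.3 = 0.667 > 0.5 -> concentration dropped;
  # |0.3 - 0.4| / 0.35 = 0.286 -> kept
  expect_false(1e-7 %in% out$concentration)
  expect_setequal(out$value[out$concentration == 1e-6], c(0.3, 0.4))
})

test_that("filters are idempotent and never add values", {
  withr::with_seed(21, {
    for (i in 1:25) {
      ser <- make_series(rep(10^(-7:-5), each = 2),
                         pmax(rnorm(6, rep(c(1, 0.7, 0.4), each = 2), 0.25),
                              0))
      once <- filter_dose_response(ser)
      twice <- filter_dose_response(once)
      cols <- c("concentration", "replicate", "value")
      expect_equal(as.data.frame(twice)[cols], as.data.frame(once)[cols],
                   ignore_attr = TRUE)
      expect_lte(nrow(once), nrow(ser))
    }
  })
})

test_that("a series emptied by filtering is flagged unusable", {
  ser <- make_series(c(1e-7, 1e-7), c(0.1, 0.9))
  out <- filter_dose_response(ser)
  expect_equal(nrow(out), 0)
  expect_true(attr(out, "unusable"))
})

test_that("interpolation is identity on-grid and linear on the log axis", {
  ser <- make_series(c(1e-7, 1e-5), c(0.4, 0.8))
  same <- interpolate_series(ser, c(1e-7, 1e-5))
  expect_equal(same$value, c(0.4, 0.8))
  mid <- interpolate_series(ser, 1e-6)  # log-midpoint
  expect_equal(mid$value, 0.6)
  expect_error(interpolate_series(ser, 1e-8), "extrapolation")
})

test_that("AUC scores match the hand-derived fixtures exactly", {
  flat1 <- make_series(10^(-7:-5), c(1, 1, 1))
  expect_identical(as.numeric(auc_score(flat1)), 0)
  flat0 <- make_series(10^(-7:-5), c(0, 0, 0))
  expect_identical(as.numeric(auc_score(flat0)), 1)
  trap <- make_series(10^(-7:-5), c(1, 0.5, 0))
  expect_equal(as.numeric(auc_score(trap)), 0.5)
  single <- make_series(1e-6, 0.5)
  expect_true(is.na(auc_score(single)))
  expect_match(attr(auc_score(single), "reason"), "fewer than 2")
})

test_that("the AUC score is linear in the response values", {
  withr::with_seed(31, {
    for (i in 1:20) {
      ser <- make_series(rep(10^(-7:-5), each = 2), runif(6, 0, 1.5))
      a <- runif(1, 0, 2)
      ser2 <- ser
      ser2$value <- a * ser$value
      s1 <- as.numeric(auc_score(ser))
      s2 <- as.numeric(auc_score(ser2))
      expect_equal(s2, 1 - a * (1 - s1), tolerance = 1e-12)
    }
  })
})

test_that("per-compound scaling uses the population-SD convention", {
  m <- matrix(c(0.2, 0.4, 0.3, 0.3), ncol = 2,
              dimnames = list(c("s1", "s2"), c("a", "b")))
  z <- scale_matrix(m)
  expect_equal(unname(z[, "a"]), c(-1, 1))
  expect_equal(unname(z[, "b"]), c(0, 0))
  expect_equal(attr(z, "constant_columns"), "b")
  withr::with_seed(5, {
    r <- matrix(rnorm(60), 12, 5)
    zr <- scale_matrix(r)
    expect_equal(unname(colMeans(zr)), rep(0, 5), tolerance = 1e-9)
    expect_equal(unname(apply(zr, 2, function(v) sqrt(mean(v^2)))),
                 rep(1, 5), tolerance = 1e-9)
  })
})

test_that("missing entries survive scaling untouched", {
  m <- matrix(c(0.2, 0.4, NA, 0.1, 0.5, 0.3), ncol = 2)
  z <- scale_matrix(m)
  expect_true(is.na(z[3, 1]))
  expect_equal(sum(is.na(z)), 1)
})

test_that("Blast AUC equals RBF-AUC on an equal-viable-count fixture", {
  # constructed so treated and control wells hold the same total viable
  # count and off-target kill is zero: the two normalizations coincide
  controls <- make_summary(rep("DMSO", 2), NA, NA, c(200, 200), c(100, 100),
                           c(60, 60))
  treated <- make_summary(rep("drugA", 6), rep(10^(-7:-5), each = 2),
                          rep(1:2, 3), rep(200, 6), rep(100, 6),
                          c(60, 60, 30, 30, 15, 15))
  ws <- rbind(controls, treated)
  ws$sample_id <- "S1"
  class(ws) <- c("well_summary", "data.frame")
  rbf <- score_cohort(ws, "rbf-auc")
  blast <- score_cohort(ws, "blast-auc")
  expect_equal(as.numeric(rbf["S1", "drugA"]),
               as.numeric(blast["S1", "drugA"]), tolerance = 1e-12)
})

test_that("cohort scoring recovers planted potency ordering", {
  tc <- tiny_cohort(seed = 12, n_samples = 10)
  ws <- simulate_well_summaries(tc$layout, tc$truth, assay_config(), seed = 12)
  rbf <- score_cohort(ws, "rbf-auc")
  rhos <- vapply(colnames(rbf), function(cmp) {
    suppressWarnings(cor(tc$truth$expected_midkill[, cmp], rbf[, cmp],
                         method = "spearman"))
  }, numeric(1))
  expect_gt(median(rhos), 0.8)
})
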