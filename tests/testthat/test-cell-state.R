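test_that("variable-region selection matches a brute-force variance sort", {
  withr::with_seed(2, {
    m <- matrix(rnorm(500), 50, 10,
                dimnames = list(sprintf("r%02d", 1:50), NULL))
    sel <- select_variable_regions(m, 12)
    v <- oracle_row_vars(m)
    expect_setequal(sel, names(sort(v, decreasing = TRUE))[1:12])
  })
  expect_error(select_variable_regions(matrix(0, 3, 2), 5), "exceeds")
})

test_that("constant regions are never selected while varying ones remain", {
  m <- rbind(flat = rep(5, 6), a = rnorm(6), b = rnorm(6))
  expect_false("flat" %in% select_variable_regions(m, 2))
  expect_setequal(select_variable_regions(m, 3), c("flat", "a", "b"))
})

test_that("the state classifier separates strong synthetic signatures", {
  truth <- simulate_cohort_truth(cohort_config(n_samples = 6), seed = 3)
  rmx <- simulate_region_matrix(truth, region_config(), seed = 3)
  lab <- rmx$reference_labels
  hold <- unlist(lapply(split(seq_along(lab), lab), utils::head, 2))
  clf <- fit_state_classifier(rmx$reference[, -hold], lab[-hold],
                              config = list(seed = 1))
  pred <- predict_state_probabilities(clf, rmx$reference[, hold])
  expect_gte(mean(pred$predicted == lab[hold]), 0.9)
})

test_that("label permutation and zero signatures collapse accuracy to chance", {
  truth <- simulate_cohort_truth(cohort_config(n_samples = 6), seed = 3)
  lab_acc <- function(rmx, labels) {
    lab <- labels
    hold <- unlist(lapply(split(seq_along(lab), rmx$reference_labels),
                          utils::head, 2))
    clf <- fit_state_classifier(rmx$reference[, -hold], lab[-hold],
                                config = list(seed = 1))
    pred <- predict_state_probabilities(clf, rmx$reference[, hold])
    mean(pred$predicted == rmx$reference_labels[hold])
  }
  rmx0 <- simulate_region_matrix(truth, region_config(signature_log2fc = 0),
                                 seed = 3)
  acc0 <- lab_acc(rmx0, rmx0$reference_labels)
  # 16 held-out samples, 8 classes: chance 1/8 plus binomial noise
  expect_lte(acc0, 1 / 8 + 4 * sqrt((1 / 8) * (7 / 8) / 16))
  rmx <- simulate_region_matrix(truth, region_config(), seed = 3)
  perm <- withr::with_seed(5, sample(rmx$reference_labels))
  accp <- lab_acc(rmx, perm)
  expect_lte(accp, 1 / 8 + 4 * sqrt((1 / 8) * (7 / 8) / 16))
})

test_that("deliberately overlapping classes concentrate the confusion", {
  # types A and B share one accessibility signature; C is distinct
  withr::with_seed(11, {
    nr <- 400
    base <- rlnorm(nr, log(100), 0.6)
    sig_ab <- 1:40
    sig_c <- 41:80
    mu <- function(sig) {
      m <- base
      m[sig] <- m[sig] * 4
      m
    }
    mus <- list(A = mu(sig_ab), B = mu(sig_ab), C = mu(sig_c))
    labels <- rep(c("A", "B", "C"), each = 8)
    ref <- vapply(seq_along(labels), function(j) {
      rnbinom(nr, mu = mus[[labels[j]]], size = 20)
    }, numeric(nr))
    rownames(ref) <- sprintf("r%03d", seq_len(nr))
  })
  hold <- c(1:3, 9:11, 17:19)
  clf <- fit_state_classifier(ref[, -hold], labels[-hold],
                              config = list(k = 200, seed = 1))
  pred <- predict_state_probabilities(clf, ref[, hold])
  wrong <- pred$predicted != labels[hold]
  # C is always right; all errors stay within the A/B pair
  expect_true(all(pred$predicted[labels[hold] == "C"] == "C"))
  if (any(wrong)) {
    expect_true(all(labels[hold][wrong] %in% c("A", "B") &
                      pred$predicted[wrong] %in% c("A", "B")))
  }
})

test_that("classifier probabilities are calibrated distributions", {
  truth <- simulate_cohort_truth(cohort_config(n_samples = 10), seed = 6)
  rmx <- simulate_region_matrix(truth, region_config(n_regions = 500,
                                                     n_signature = 30),
                                seed = 6)
  clf <- fit_state_classifier(rmx$reference, rmx$reference_labels,
                              config = list(seed = 2))
  pred <- predict_state_probabilities(clf, rmx$cohort)
  expect_equal(unname(rowSums(pred$probabilities)),
               rep(1, 10), tolerance = 1e-9)
  expect_true(all(pred$probabilities >= 0))
  # noise-free class centroid maps to its own class
  centroid <- matrix(rowMeans(rmx$reference[, rmx$reference_labels == "GMP"]),
                     ncol = 1, dimnames = list(rownames(rmx$reference), "x"))
  pc <- predict_state_probabilities(clf, centroid)
  expect_equal(pc$predicted, "GMP")
  # empty cohort gives an empty result
  empty <- rmx$cohort[, 0, drop = FALSE]
  expect_equal(nrow(predict_state_probabilities(clf, empty)$probabilities), 0)
})

test_that("single-sample classes and region mismatches are rejected", {
  m <- matrix(rpois(60, 50), 10, 6,
              dimnames = list(sprintf("r%d", 1:10), NULL))
  expect_error(fit_state_classifier(m, c("A", "A", "A", "B", "B", "C")),
               "C")
  clf <- fit_state_classifier(m, rep(c("A", "B"), each = 3),
                              config = list(k = 5))
  bad <- m[1:5, ]
  rownames(bad) <- sprintf("other%d", 1:5)
  expect_error(predict_state_probabilities(clf, bad), "missing training regions")
})

test_that("the Mono-HSC propensity score follows the cohort-maximum formula", {
  pr <- cbind(monocyte = c(0.4, 0.2, 0.1), HSC = c(0.1, 0.05, 0.5),
              GMP = c(0.5, 0.75, 0.4))
  rownames(pr) <- c("s1", "s2", "s3")
  sc <- mono_hsc_propensity(pr)
  expect_equal(unname(sc), c(1.0, 0.5, 1.0))
  expect_true(all(sc > 0 & sc <= 1))
  # scale invariance of the ratios
  pr2 <- pr
  pr2[, "monocyte"] <- pr2[, "monocyte"] * 7
  expect_equal(mono_hsc_propensity(pr2), sc)
  # single-sample cohorts score 1 by self-maximum
  expect_equal(unname(mono_hsc_propensity(pr[1, , drop = FALSE])), 1)
  pr0 <- pr
  pr0[, "HSC"] <- 0
  expect_error(mono_hsc_propensity(pr0), "undefined")
})

test_that("the rank-sum association test matches exact enumeration", {
  res <- association_test(c(1, 2, 3, 4, 5, 6),
                          rep(c("a", "b"), each = 3))
  expect_equal(res$p_value, 0.1)   # complete separation, 2 / C(6,3)
  expect_equal(res$method, "exact")
  withr::with_seed(29, {
    for (i in 1:12) {
      n1 <- sample(2:6, 1)
      n2 <- sample(2:6, 1)
      g1 <- rnorm(n1)
      g2 <- rnorm(n2, 0.5)
      res <- association_test(c(g1, g2), rep(c("x", "y"), c(n1, n2)))
      expect_equal(res$p_value, oracle_mw_p(g1, g2), tolerance = 1e-12)
    }
  })
})

test_that("identical groups are null and empty groups error", {
  res <- association_test(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(res$p_value, 1)
  expect_error(association_test(1:3, rep("a", 3)), "2 nonempty groups")
})
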