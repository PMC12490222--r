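clin_fixture <- function() {
  data.frame(
    sample_id = sprintf("S%02d", 1:8),
    mrd1 = c("pos", "pos", "neg", "not-determined", "neg", "pos", "neg",
             "pos"),
    mrd1_percent = c(5, 0.4, 0.01, NA, 0.02, 1, 0.05, 2.5),
    mrd2 = "neg",
    risk = c("SR", "IR", "HR", "SR", "IR", "HR", "SR", "IR"),
    relapse_day = c(300, NA, 400, NA, NA, 200, NA, 800),
    followup_day = c(300, 200, 900, 1200, 400, 200, 100, 900),
    stringsAsFactors = FALSE
  )
}

test_that("MRD 1% labels exclude non-determined samples", {
  lab <- make_binary_labels(clin_fixture(), "mrd1_1pct")
  expect_equal(sum(lab$evaluable), 7)
  expect_true(is.na(lab$labels[["S04"]]))
  expect_equal(as.character(lab$labels[c("S01", "S02", "S06")]),
               c("pos", "neg", "pos"))  # 1% is inclusive
})

test_that("non-standard risk is IR or HR and always evaluable", {
  lab <- make_binary_labels(clin_fixture(), "non_standard_risk")
  expect_true(all(lab$evaluable))
  expect_equal(as.character(lab$labels[c("S01", "S02", "S03")]),
               c("neg", "pos", "pos"))
})

test_that("early relapse uses the 365-day cut with a follow-up guard", {
  lab <- make_binary_labels(clin_fixture(), "early_relapse")
  expect_equal(as.character(lab$labels[["S01"]]), "pos")   # day 300
  expect_equal(as.character(lab$labels[["S03"]]), "neg")   # day 400
  expect_equal(as.character(lab$labels[["S08"]]), "neg")   # day 800
  expect_true(is.na(lab$labels[["S02"]]))   # no relapse, 200 days follow-up
  expect_true(is.na(lab$labels[["S07"]]))
  expect_false(lab$evaluable[7])
  expect_error(make_binary_labels(clin_fixture(), "overall_survival"))
})

test_that("label construction is independent of row order", {
  cl <- clin_fixture()
  a <- make_binary_labels(cl, "early_relapse")
  perm <- c(5, 2, 8, 1, 3, 7, 4, 6)
  b <- make_binary_labels(cl[perm, ], "early_relapse")
  expect_identical(a$labels[cl$sample_id], b$labels[cl$sample_id])
})

test_that("cross-validated forests are deterministic and seed-sensitive", {
  withr::with_seed(7, {
    x <- matrix(rnorm(40 * 8), 40, 8,
                dimnames = list(sprintf("S%02d", 1:40), letters[1:8]))
    y <- factor(ifelse(x[, 1] + rnorm(40, 0, 0.5) > 0, "pos", "neg"),
                c("neg", "pos"))
  })
  names(y) <- rownames(x)
  r1 <- cross_validated_accuracy(x, y, seed = 3)
  r2 <- cross_validated_accuracy(x, y, seed = 3)
  expect_identical(r1$fold_accuracy, r2$fold_accuracy)
  expect_identical(r1$importance, r2$importance)
  expect_equal(sum(r1$importance), 1)
  expect_true(all(r1$fold_accuracy >= 0 & r1$fold_accuracy <= 1))
})

test_that("a perfectly separating compound dominates the importances", {
  withr::with_seed(9, {
    x <- matrix(rnorm(30 * 10), 30, 10,
                dimnames = list(sprintf("S%02d", 1:30),
                                sprintf("d%02d", 1:10)))
    y <- factor(rep(c("neg", "pos"), each = 15), c("neg", "pos"))
    x[, "d03"] <- ifelse(y == "pos", 1, -1) + rnorm(30, 0, 0.05)
  })
  names(y) <- rownames(x)
  tab <- importance_vs_inhibition(x, y, seed = 2)
  expect_equal(nrow(tab), 10)
  expect_equal(tab$compound[which.max(tab$importance)], "d03")
  expect_gt(tab$delta_z[tab$compound == "d03"], 1.5)
  # a compound with identical group distributions has delta-z near zero
  expect_lt(abs(tab$delta_z[tab$compound == "d01"]), 0.8)
})

test_that("increasing the planted effect never lowers median CV accuracy", {
  med_acc <- function(effect) {
    accs <- vapply(1:5, function(seed) {
      withr::with_seed(100 + seed, {
        x <- matrix(rnorm(30 * 6), 30, 6)
        rownames(x) <- sprintf("S%02d", 1:30)
        colnames(x) <- letters[1:6]
        y <- factor(ifelse(effect * x[, 1] + rnorm(30) > 0, "pos", "neg"),
                    c("neg", "pos"))
        names(y) <- rownames(x)
      })
      if (min(table(y)) < 2) return(NA_real_)
      cross_validated_accuracy(x, y, seed = seed)$mean_accuracy
    }, numeric(1))
    median(accs, na.rm = TRUE)
  }
  a0 <- med_acc(0)
  a1 <- med_acc(1.5)
  a2 <- med_acc(6)
  expect_lte(a0, a1 + 0.05)
  expect_lte(a1, a2 + 0.05)
})

test_that("degenerate label sets are rejected with guidance", {
  x <- matrix(rnorm(20), 10, 2)
  rownames(x) <- sprintf("S%02d", 1:10)
  y <- factor(c("pos", rep("neg", 9)), c("neg", "pos"))
  names(y) <- rownames(x)
  expect_error(cross_validated_accuracy(x, y), "2 evaluable samples per class")
})
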