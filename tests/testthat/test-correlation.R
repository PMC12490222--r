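test_that("the activity filter counts qualifying samples inclusively", {
  m <- matrix(0.1, 6, 3, dimnames = list(sprintf("s%d", 1:6), c("a", "b", "c")))
  m[1:3, "a"] <- c(0.30, 0.26, 0.25)   # exactly 3 at/above 0.25 -> kept
  m[1:2, "b"] <- c(0.30, 0.26)         # only 2 -> dropped
  m[1:4, "c"] <- c(0.9, NA, 0.5, 0.25) # missing entries do not count
  expect_setequal(activity_filter(m), c("a", "c"))
  expect_setequal(activity_filter(m, threshold = 0, min_samples = 0),
                  c("a", "b", "c"))
  expect_error(activity_filter(matrix(numeric(0), 0, 0)), "empty")
})

test_that("the activity filter is invariant to row and column permutations", {
  withr::with_seed(3, {
    m <- matrix(runif(40, 0, 0.6), 8, 5,
                dimnames = list(sprintf("s%d", 1:8), sprintf("d%d", 1:5)))
    kept <- activity_filter(m)
    mp <- m[sample(8), sample(5)]
    expect_setequal(activity_filter(mp), kept)
  })
})

test_that("self- and anti-correlations hit the rank extremes", {
  m <- cbind(a = 1:6, b = 6:1, c = c(2, 4, 6, 1, 3, 5))
  res <- pairwise_spearman(m)
  expect_equal(unname(diag(res$rho)), rep(1, 3))
  expect_equal(res$rho["a", "b"], -1)
  expect_true(isSymmetric(res$rho))
})

test_that("rho, p and BH q match the brute-force oracle to 1e-12", {
  withr::with_seed(17, {
    for (rep in 1:6) {
      n <- sample(4:6, 1)
      d <- sample(6:10, 1)
      m <- matrix(rnorm(n * d), n, d,
                  dimnames = list(NULL, sprintf("c%d", seq_len(d))))
      res <- pairwise_spearman(m)
      prs <- t(combn(d, 2))
      p_oracle <- rho_oracle <- numeric(nrow(prs))
      for (k in seq_len(nrow(prs))) {
        i <- prs[k, 1]; j <- prs[k, 2]
        rho_oracle[k] <- oracle_spearman_rho(m[, i], m[, j])
        p_oracle[k] <- oracle_spearman_p(m[, i], m[, j])
        expect_equal(res$rho[i, j], rho_oracle[k], tolerance = 1e-12)
        expect_equal(res$p[i, j], p_oracle[k], tolerance = 1e-12)
      }
      q_oracle <- oracle_bh(p_oracle)
      for (k in seq_len(nrow(prs))) {
        expect_equal(res$q[prs[k, 1], prs[k, 2]], q_oracle[k],
                     tolerance = 1e-12)
      }
    }
  })
})

test_that("the t-approximation route also matches the oracle at n >= 10", {
  withr::with_seed(19, {
    m <- matrix(rnorm(10 * 4), 10, 4, dimnames = list(NULL, letters[1:4]))
    res <- pairwise_spearman(m)
    expect_equal(res$p["a", "b"], oracle_spearman_p(m[, "a"], m[, "b"]),
                 tolerance = 1e-12)
  })
})

test_that("constant columns and short overlaps are recorded missing", {
  m <- cbind(a = c(1, 2, 3, 4), b = c(2, 2, 2, 2), c = c(1, NA, NA, 2))
  res <- pairwise_spearman(m)
  expect_true(is.na(res$rho["a", "b"]))
  expect_true(is.na(res$rho["a", "c"]))  # only 2 complete pairs
})

test_that("class-pair consistency follows the all-same-sign rule", {
  ids <- c("h1", "h2", "v1", "f1")
  ann <- data.frame(compound = ids,
                    class = c("HDAC", "HDAC", "VEN", "FLT3"))
  rho <- matrix(NA_real_, 4, 4, dimnames = list(ids, ids))
  diag(rho) <- 1
  rho["h1", "v1"] <- rho["v1", "h1"] <- 0.5
  rho["h2", "v1"] <- rho["v1", "h2"] <- 0.7
  rho["f1", "v1"] <- rho["v1", "f1"] <- -0.4
  rho["h1", "f1"] <- rho["f1", "h1"] <- 0.5
  rho["h2", "f1"] <- rho["f1", "h2"] <- -0.1
  q <- rho * 0 + 0.01
  res <- class_consistency(list(rho = rho, q = q), ann)
  hv <- res[res$class_a == "HDAC" & res$class_b == "VEN", ]
  expect_true(hv$consistent)
  expect_equal(hv$sign, "positive")
  expect_equal(hv$mean_rho, 0.6)
  expect_equal(hv$n_pairs, 2)
  expect_equal(hv$frac_significant, 1)
  hf <- res[res$class_a == "FLT3" & res$class_b == "HDAC", ]
  expect_false(hf$consistent)  # mixed signs 0.5 and -0.1
  expect_equal(hf$sign, "none")
  fv <- res[res$class_a == "FLT3" & res$class_b == "VEN", ]
  expect_true(fv$consistent)   # single negative pair
  expect_equal(fv$sign, "negative")
  expect_equal(fv$mean_rho, -0.4)
})

test_that("adding a same-sign pair never flips consistency; opposite always does", {
  withr::with_seed(23, {
    for (i in 1:10) {
      n_a <- sample(2:4, 1)
      ids <- c(sprintf("a%d", seq_len(n_a)), "b1")
      ann <- data.frame(compound = ids,
                        class = c(rep("A", n_a), "B"))
      rho <- matrix(NA_real_, length(ids), length(ids),
                    dimnames = list(ids, ids))
      diag(rho) <- 1
      vals <- runif(n_a, 0.1, 0.9)
      for (k in seq_len(n_a)) {
        rho[sprintf("a%d", k), "b1"] <- rho["b1", sprintf("a%d", k)] <- vals[k]
      }
      q <- rho * 0 + 1
      base <- class_consistency(list(rho = rho, q = q), ann)
      expect_true(base$consistent)
      # flip one pair's sign: consistency must break
      rho2 <- rho
      rho2["a1", "b1"] <- rho2["b1", "a1"] <- -vals[1]
      broke <- class_consistency(list(rho = rho2, q = q), ann)
      expect_false(broke$consistent)
      # a zero also breaks it
      rho3 <- rho
      rho3["a1", "b1"] <- rho3["b1", "a1"] <- 0
      expect_false(class_consistency(list(rho = rho3, q = q), ann)$consistent)
    }
  })
})

test_that("annotation must cover every compound in the matrix", {
  rho <- diag(2)
  dimnames(rho) <- list(c("x", "y"), c("x", "y"))
  expect_error(
    class_consistency(list(rho = rho, q = rho),
                      data.frame(compound = "x", class = "A")),
    "does not cover")
})
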