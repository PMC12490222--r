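#' Log2 counts-per-million normalization of a region count matrix
#'
#' @param matrix regions x samples count matrix.
#' @return `log2(CPM + 1)` matrix of the same shape.
#' @export
normalize_region_counts <- function(matrix) {
  m <- as.matrix(matrix)
  lib <- colSums(m)
  lib[lib == 0] <- 1
  log2(sweep(m, 2, lib, "/") * 1e6 + 1)
}

#' Select the most variable regions
#'
#' Returns the `k` regions with the highest variance across samples of the
#' supplied (reference) matrix; ties are broken by region id so the
#' selection is deterministic.
#'
#' @param matrix regions x samples matrix (rownames = region ids).
#' @param k Number of regions (default 1000).
#' @return Character vector of `k` region ids.
#' @export
select_variable_regions <- function(matrix, k = 1000) {
  m <- as.matrix(matrix)
  if (k > nrow(m)) {
    stop("k (", k, ") exceeds the number of regions (", nrow(m), ")")
  }
  ids <- rownames(m) %||% sprintf("region_%05d", seq_len(nrow(m)))
  v <- apply(m, 1, var)
  ids[order(-v, ids)][seq_len(k)]
}

#' Fit the healthy cell-state classifier
#'
#' Trains a support-vector classifier with a radial-basis kernel and
#' balanced class weights on the `k` most variable consensus regions of a
#' labeled healthy reference (counts are log2-CPM normalized first).
#' Probabilities come from one-vs-rest decision values passed through
#' seeded 3-fold cross-validated Platt sigmoid calibration and normalized
#' to sum to one, which keeps the whole fit deterministic under a fixed
#' seed.
#'
#' @param reference regions x samples count matrix of the healthy
#'   reference.
#' @param labels Cell-type label per reference sample (>= 2 classes with
#'   >= 2 samples each).
#' @param config Optional list: `k` variable regions (default 1000,
#'   capped at the region count), `cost` (default 1), `gamma` (default
#'   `1/k`), `calibration_folds` (default 3), `seed` (default 1),
#'   `normalize` (default TRUE).
#' @return An object of class `state_classifier`.
#' @export
fit_state_classifier <- function(reference, labels, config = list()) {
  labels <- as.character(labels)
  stopifnot(ncol(reference) == length(labels))
  tab <- table(labels)
  if (length(tab) < 2) stop("at least 2 reference classes are required")
  if (any(tab < 2)) {
    stop("reference class with a single sample: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  }
  k <- min(config$k %||% 1000, nrow(reference))
  seed <- config$seed %||% 1
  folds <- config$calibration_folds %||% 3
  normalize <- config$normalize %||% TRUE

  norm <- if (normalize) normalize_region_counts(reference) else
    as.matrix(reference)
  regions <- select_variable_regions(norm, k)
  x <- t(norm[regions, , drop = FALSE])
  classes <- sort(names(tab))
  cost <- config$cost %||% 1
  gamma <- config$gamma %||% (1 / k)

  # per-class one-vs-rest machines + Platt calibration on held-out
  # decision values
  machines <- list()
  platt <- list()
  fold_id <- with_seed(stream_seed(seed, "calibration"), {
    f <- integer(length(labels))
    for (cl in classes) {
      idx <- which(labels == cl)
      f[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    f
  })
  for (cl in classes) {
    y <- factor(ifelse(labels == cl, "pos", "neg"), c("neg", "pos"))
    w <- length(y) / (2 * table(y))
    machines[[cl]] <- e1071::svm(x, y, kernel = "radial", cost = cost,
                                 gamma = gamma, class.weights = w,
                                 scale = FALSE)
    dv_cv <- rep(NA_real_, length(y))
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      if (length(unique(y[tr])) < 2) next
      mfit <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "radial",
                         cost = cost, gamma = gamma,
                         class.weights = length(y[tr]) / (2 * table(y[tr])),
                         scale = FALSE)
      dv_cv[!tr] <- .decision_pos(mfit, x[!tr, , drop = FALSE])
    }
    ok <- !is.na(dv_cv)
    # Platt's smoothed targets keep the sigmoid finite when the folds are
    # perfectly separable
    np <- sum(y[ok] == "pos")
    nn <- sum(y[ok] == "neg")
    t_smooth <- ifelse(y[ok] == "pos", (np + 1) / (np + 2), 1 / (nn + 2))
    cal <- suppressWarnings(
      glm(t_smooth ~ dv, family = quasibinomial(),
          data = data.frame(t_smooth = t_smooth, dv = dv_cv[ok]))
    )
    platt[[cl]] <- coef(cal)
  }
  structure(list(
    machines = machines, platt = platt, classes = classes,
    regions = regions, normalize = normalize,
    config = list(k = k, cost = cost, gamma = gamma, seed = seed,
                  calibration_folds = folds)
  ), class = "state_classifier")
}

# decision value oriented so that larger = more "pos"
.decision_pos <- function(machine, x) {
  pr <- predict(machine, x, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  sgn <- if (grepl("^pos", colnames(dv)[1])) 1 else -1
  sgn * as.numeric(dv[, 1])
}

#' @export
print.state_classifier <- function(x, ...) {
  cat(sprintf(
    "<state_classifier> RBF-kernel SVM, %d classes, %d variable regions\n",
    length(x$classes), length(x$regions)))
  invisible(x)
}

#' Project cohort samples onto healthy cell states
#'
#' Applies the state classifier to a cohort region-count matrix (same
#' region index as the training reference) and returns calibrated
#' per-sample probabilities over the healthy cell types, plus the argmax
#' predicted state.
#'
#' @param classifier A [fit_state_classifier()] result.
#' @param cohort regions x samples count matrix.
#' @return A list of class `cell_state_probabilities` with
#'   `probabilities` (samples x classes, rows sum to 1) and `predicted`.
#' @export
predict_state_probabilities <- function(classifier, cohort) {
  stopifnot(inherits(classifier, "state_classifier"))
  m <- as.matrix(cohort)
  if (ncol(m) == 0) {
    pr <- matrix(numeric(0), 0, length(classifier$classes),
                 dimnames = list(NULL, classifier$classes))
    return(structure(list(probabilities = pr, predicted = character(0)),
                     class = "cell_state_probabilities"))
  }
  miss <- setdiff(classifier$regions, rownames(m))
  if (length(miss)) {
    stop("cohort matrix is missing training regions: ",
         paste(head(miss, 5), collapse = ", "),
         if (length(miss) > 5) sprintf(" (+%d more)", length(miss) - 5))
  }
  norm <- if (classifier$normalize) normalize_region_counts(m) else m
  x <- t(norm[classifier$regions, , drop = FALSE])
  raw <- vapply(classifier$classes, function(cl) {
    dv <- .decision_pos(classifier$machines[[cl]], x)
    b <- classifier$platt[[cl]]
    plogis(b[1] + b[2] * dv)
  }, numeric(nrow(x)))
  if (nrow(x) == 1L) raw <- matrix(raw, nrow = 1,
                                   dimnames = list(NULL, classifier$classes))
  prob <- raw / rowSums(raw)
  rownames(prob) <- colnames(m)
  structure(list(
    probabilities = prob,
    predicted = colnames(prob)[max.col(prob, ties.method = "first")]
  ), class = "cell_state_probabilities")
}

#' @export
print.cell_state_probabilities <- function(x, ...) {
  cat(sprintf("<cell_state_probabilities> %d samples x %d states\n",
              nrow(x$probabilities), ncol(x$probabilities)))
  if (nrow(x$probabilities)) print(table(x$predicted))
  invisible(x)
}

#' Mono-HSC propensity score
#'
#' Quantifies how far each sample deviates from the cohort's average
#' phenotype toward either differentiation extreme:
#' `score_s = max(P_mono,s / max_t P_mono,t, P_HSC,s / max_t P_HSC,t)`,
#' with the maxima taken over the cohort passed in. Scores lie in (0, 1]
#' and at least one sample attains 1 on each fully attained side.
#'
#' @param probabilities A [predict_state_probabilities()] result or a
#'   samples x states probability matrix.
#' @param mono,hsc Column names of the monocyte and HSC states.
#' @return Named numeric vector of propensity scores.
#' @export
mono_hsc_propensity <- function(probabilities, mono = "monocyte",
                                hsc = "HSC") {
  pr <- if (inherits(probabilities, "cell_state_probabilities")) {
    probabilities$probabilities
  } else {
    as.matrix(probabilities)
  }
  stopifnot(all(c(mono, hsc) %in% colnames(pr)))
  pm <- pr[, mono]
  ph <- pr[, hsc]
  if (max(pm) <= 0 || max(ph) <= 0) {
    stop("propensity score undefined: cohort maximum of P_mono or P_HSC is zero")
  }
  setNames(pmax(pm / max(pm), ph / max(ph)), rownames(pr))
}

#' Mann-Whitney association between a score and a binary grouping
#'
#' Rank-sum test of the score between the two label groups: exact
#' p-value when both groups have at most 8 observations and the scores
#' are tie-free, normal approximation with tie correction (and continuity
#' correction) otherwise. The reported U statistic is the rank-sum of the
#' first group minus `n1 (n1 + 1) / 2`.
#'
#' @param scores Numeric vector.
#' @param labels Binary grouping aligned with `scores` (factor, logical or
#'   two-level vector).
#' @param exact_max Largest group size for the exact route (default 8).
#' @return A list with `U`, `p_value`, `method` and the group sizes.
#' @export
association_test <- function(scores, labels, exact_max = 8) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2) {
    stop("labels must define exactly 2 nonempty groups")
  }
  labels <- droplevels(labels)
  g1 <- scores[labels == levels(labels)[1]]
  g2 <- scores[labels == levels(labels)[2]]
  if (!length(g1) || !length(g2)) stop("one group is empty")
  ties <- anyDuplicated(c(g1, g2)) > 0
  exact <- length(g1) <= exact_max && length(g2) <= exact_max && !ties
  ht <- suppressWarnings(
    wilcox.test(g1, g2, exact = exact, correct = !exact)
  )
  list(U = unname(ht$statistic), p_value = ht$p.value,
       method = if (exact) "exact" else "normal approximation",
       n = c(length(g1), length(g2)),
       groups = levels(labels))
}
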