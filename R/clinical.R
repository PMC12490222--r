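#' Build binary clinical endpoint labels
#'
#' Constructs the binary targets predicted from sensitivity profiles:
#' * `mrd1_1pct` — positive when the measurable-residual-disease burden
#'   after the first induction is at least 1% blasts; samples whose MRD1
#'   was not determined are excluded.
#' * `non_standard_risk` — positive when the risk group is IR or HR
#'   (i.e. not SR); all samples with a risk group are evaluable.
#' * `early_relapse` — positive when relapse occurred within 365 days of
#'   diagnosis; samples with neither a relapse nor at least 365 days of
#'   follow-up are excluded (insufficient observation time).
#'
#' Label construction is pure: it depends only on the clinical fields,
#' not on row order.
#'
#' @param clinical Clinical table ([clinical_labels()] layout): columns
#'   `sample_id`, `mrd1`, `mrd1_percent`, `risk`, `relapse_day`,
#'   `followup_day`.
#' @param endpoint One of `"mrd1_1pct"`, `"non_standard_risk"`,
#'   `"early_relapse"`.
#' @return A list with `labels` (factor `neg`/`pos` named by sample id,
#'   `NA` for non-evaluable samples) and `evaluable` (logical mask).
#' @export
make_binary_labels <- function(clinical, endpoint = c("mrd1_1pct",
                                                      "non_standard_risk",
                                                      "early_relapse")) {
  endpoint <- match.arg(endpoint)
  n <- nrow(clinical)
  pos <- rep(NA, n)
  if (endpoint == "mrd1_1pct") {
    evaluable <- clinical$mrd1 %in% c("pos", "neg") &
      !is.na(clinical$mrd1_percent)
    pos[evaluable] <- clinical$mrd1_percent[evaluable] >= 1
  } else if (endpoint == "non_standard_risk") {
    evaluable <- !is.na(clinical$risk)
    pos[evaluable] <- clinical$risk[evaluable] %in% c("IR", "HR")
  } else {
    relapsed <- !is.na(clinical$relapse_day)
    evaluable <- relapsed | clinical$followup_day >= 365
    pos[evaluable] <- relapsed[evaluable] &
      clinical$relapse_day[evaluable] <= 365
    pos[evaluable & relapsed & clinical$relapse_day > 365] <- FALSE
  }
  labels <- factor(ifelse(pos, "pos", "neg"), levels = c("neg", "pos"))
  names(labels) <- clinical$sample_id
  list(labels = labels, evaluable = evaluable, endpoint = endpoint)
}

#' Random-forest settings used for clinical prediction
#'
#' 101 trees, each grown on the complete training set (no bootstrap
#' resampling), with class weights inversely proportional to class
#' frequency.
#'
#' @param num_trees Number of trees (default 101).
#' @param folds Cross-validation folds (default 5).
#' @return A list of class `forest_config`.
#' @export
forest_config <- function(num_trees = 101, folds = 5) {
  structure(list(num_trees = num_trees, folds = folds),
            class = "forest_config")
}

.fit_forest <- function(x, y, config, seed) {
  w <- as.numeric(length(y) / (nlevels(y) * table(y)))
  ranger::ranger(
    x = x, y = y,
    num.trees = config$num_trees,
    replace = FALSE, sample.fraction = 1,
    class.weights = w,
    importance = "impurity",
    seed = seed, num.threads = 1
  )
}

# Seeded stratified fold assignment; errors when a training fold would be
# single-class.
.stratified_folds <- function(y, folds, seed) {
  f <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      f[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  for (k in seq_len(folds)) {
    if (length(unique(y[f != k])) < 2) {
      stop("a training fold contains a single class; use fewer folds")
    }
  }
  f
}

#' Cross-validated prediction of a clinical endpoint
#'
#' Stratified seeded k-fold cross-validation of a random forest
#' ([forest_config()] settings) predicting a binary clinical label from
#' the samples x compounds sensitivity matrix. Reports per-fold held-out
#' accuracies, their mean, and normalized feature importances from a
#' forest fit on all evaluable samples.
#'
#' @param sensitivity_matrix samples x compounds score matrix (row names
#'   matching the label names).
#' @param labels A [make_binary_labels()] result (or named factor with
#'   `NA` for non-evaluable samples).
#' @param config A [forest_config()].
#' @param seed Integer seed controlling folds and forests.
#' @return An object of class `prediction_result`: `endpoint`,
#'   `fold_accuracy`, `mean_accuracy`, `importance` (nonnegative, sums
#'   to 1), `n_evaluable`.
#' @export
cross_validated_accuracy <- function(sensitivity_matrix, labels,
                                     config = forest_config(), seed = 1) {
  lab <- if (is.list(labels)) labels$labels else labels
  m <- as.matrix(sensitivity_matrix)
  keep <- !is.na(lab)
  if (!is.null(names(lab)) && !is.null(rownames(m))) {
    stopifnot(all(names(lab) %in% rownames(m)))
    m <- m[names(lab), , drop = FALSE]
  }
  y <- droplevels(lab[keep])
  x <- m[keep, , drop = FALSE]
  x[is.na(x)] <- 0
  if (nlevels(y) < 2 || any(table(y) < 2)) {
    stop("at least 2 evaluable samples per class are required")
  }
  folds <- config$folds
  f <- .stratified_folds(y, folds, stream_seed(seed, "folds"))
  acc <- numeric(folds)
  for (k in seq_len(folds)) {
    fit <- .fit_forest(x[f != k, , drop = FALSE], y[f != k], config,
                       stream_seed(seed, paste0("fold", k)))
    pred <- predict(fit, data = x[f == k, , drop = FALSE],
                    num.threads = 1)$predictions
    acc[k] <- mean(pred == y[f == k])
  }
  full <- .fit_forest(x, y, config, stream_seed(seed, "full"))
  imp <- full$variable.importance
  imp <- pmax(imp, 0)
  imp <- if (sum(imp) > 0) imp / sum(imp) else imp
  structure(list(
    endpoint = if (is.list(labels)) labels$endpoint else NA_character_,
    fold_accuracy = acc, mean_accuracy = mean(acc),
    importance = imp, n_evaluable = length(y)
  ), class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf(
    "<prediction_result> %s: mean accuracy %.3f over %d folds (n = %d)\n",
    x$endpoint %||% "endpoint", x$mean_accuracy, length(x$fold_accuracy),
    x$n_evaluable))
  cat("  per fold:", paste(sprintf("%.3f", x$fold_accuracy), collapse = " "),
      "\n")
  invisible(x)
}

#' Relate forest feature importance to group-wise inhibition differences
#'
#' Fits one forest on all evaluable samples and, per compound, reports the
#' normalized importance next to the difference in mean z-scaled
#' inhibition between the positive and negative label groups
#' (`delta_z = mean(z | pos) - mean(z | neg)` on the per-compound scaled
#' matrix; constant compounds get `delta_z = 0`).
#'
#' @inheritParams cross_validated_accuracy
#' @return A data.frame with one row per compound: `compound`,
#'   `importance`, `delta_z`.
#' @export
importance_vs_inhibition <- function(sensitivity_matrix, labels,
                                     config = forest_config(), seed = 1) {
  lab <- if (is.list(labels)) labels$labels else labels
  m <- as.matrix(sensitivity_matrix)
  if (!is.null(names(lab)) && !is.null(rownames(m))) {
    m <- m[names(lab), , drop = FALSE]
  }
  keep <- !is.na(lab)
  y <- droplevels(lab[keep])
  x <- m[keep, , drop = FALSE]
  x[is.na(x)] <- 0
  fit <- .fit_forest(x, y, config, stream_seed(seed, "importance"))
  imp <- pmax(fit$variable.importance, 0)
  imp <- if (sum(imp) > 0) imp / sum(imp) else imp
  z <- scale_matrix(x)
  delta <- colMeans(z[y == "pos", , drop = FALSE], na.rm = TRUE) -
    colMeans(z[y == "neg", , drop = FALSE], na.rm = TRUE)
  delta[!is.finite(delta)] <- 0
  data.frame(compound = colnames(m), importance = as.numeric(imp),
             delta_z = as.numeric(delta), stringsAsFactors = FALSE)
}
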