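#' Keep compounds with appreciable activity
#'
#' A compound is kept when its Blast-AUC score reaches `threshold`
#' (inclusive) in at least `min_samples` samples; missing entries do not
#' count. The defaults (0.25 in at least 3 samples) correspond to roughly
#' 50% inhibition at half the concentration points in at least three
#' samples.
#'
#' @param blast_auc_matrix samples x compounds score matrix.
#' @param threshold Score threshold (default 0.25).
#' @param min_samples Minimum qualifying samples (default 3).
#' @return Character vector of kept compound ids.
#' @export
activity_filter <- function(blast_auc_matrix, threshold = 0.25,
                            min_samples = 3) {
  m <- as.matrix(blast_auc_matrix)
  if (length(m) == 0) stop("empty sensitivity matrix")
  n_active <- colSums(m >= threshold, na.rm = TRUE)
  colnames(m)[n_active >= min_samples]
}

# Exact two-sided Spearman permutation p-value machinery. The null
# distribution of rho for a given n (no ties) is cached per session.
.spearman_cache <- new.env(parent = emptyenv())

.perm_matrix <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .perm_matrix(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub))
  }
  out
}

.spearman_null_rho <- function(n) {
  key <- as.character(n)
  if (!is.null(.spearman_cache[[key]])) return(.spearman_cache[[key]])
  perms <- .perm_matrix(as.integer(n))
  d2 <- rowSums((perms - matrix(seq_len(n), nrow(perms), n, byrow = TRUE))^2)
  rho <- 1 - 6 * d2 / (n * (n^2 - 1))
  .spearman_cache[[key]] <- rho
  rho
}

# Two-sided p-value for one Spearman coefficient: exact full-permutation
# enumeration for n <= 9 without ties, t-approximation otherwise.
.spearman_pvalue <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) return(NA_real_)
  rho <- suppressWarnings(cor(x, y, method = "spearman"))
  if (is.na(rho)) return(NA_real_)
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n <= 9 && !ties) {
    null_rho <- .spearman_null_rho(n)
    return(mean(abs(null_rho) >= abs(rho) - 1e-12))
  }
  if (abs(rho) >= 1) return(0)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * pt(-abs(tstat), n - 2)
}

#' Pairwise Spearman correlations with Benjamini-Hochberg control
#'
#' Computes Spearman's rank correlation for every compound pair on
#' pairwise-complete observations (average ranks for ties). Two-sided
#' p-values use the exact full permutation distribution for n <= 9
#' complete pairs without ties, and the t-approximation otherwise.
#' Benjamini-Hochberg adjustment is applied once across all unique
#' off-diagonal pairs (a single family). Pairs with fewer than
#' `min_pairs` complete observations, or involving a constant column, are
#' recorded missing.
#'
#' @param matrix samples x compounds score matrix.
#' @param min_pairs Minimum complete observations per pair (default 3).
#' @return A list of class `drug_correlations` with symmetric matrices
#'   `rho` (unit diagonal), `p` and `q` (BH-adjusted), and a long-format
#'   `pairs` data.frame.
#' @export
pairwise_spearman <- function(matrix, min_pairs = 3) {
  m <- as.matrix(matrix)
  nc <- ncol(m)
  ids <- colnames(m) %||% as.character(seq_len(nc))
  rho <- p <- q <- matrix(NA_real_, nc, nc, dimnames = list(ids, ids))
  diag(rho) <- 1
  pairs <- t(combn(nc, 2))
  pair_rho <- pair_p <- rep(NA_real_, nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]
    j <- pairs[k, 2]
    ok <- stats::complete.cases(m[, i], m[, j])
    if (sum(ok) < min_pairs) next
    if (sd(m[ok, i]) == 0 || sd(m[ok, j]) == 0) next
    pair_rho[k] <- suppressWarnings(
      cor(m[ok, i], m[ok, j], method = "spearman"))
    pair_p[k] <- .spearman_pvalue(m[ok, i], m[ok, j])
  }
  pair_q <- rep(NA_real_, length(pair_p))
  has_p <- !is.na(pair_p)
  pair_q[has_p] <- p.adjust(pair_p[has_p], method = "BH")
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]
    j <- pairs[k, 2]
    rho[i, j] <- rho[j, i] <- pair_rho[k]
    p[i, j] <- p[j, i] <- pair_p[k]
    q[i, j] <- q[j, i] <- pair_q[k]
  }
  structure(list(
    rho = rho, p = p, q = q,
    pairs = data.frame(
      drug_a = ids[pairs[, 1]], drug_b = ids[pairs[, 2]],
      rho = pair_rho, p = pair_p, q = pair_q,
      significant = !is.na(pair_q) & pair_q < 0.05,
      stringsAsFactors = FALSE
    )
  ), class = "drug_correlations")
}

#' Drug-class pair consistency calls
#'
#' For every unordered pair of distinct drug classes, collects all
#' cross-class drug-pair correlations and calls the class pair consistent
#' when every coefficient has the same strict sign (a zero or missing
#' coefficient breaks consistency). Reports the mean coefficient and the
#' fraction of pairs significant after Benjamini-Hochberg adjustment.
#' Within-class pairs are excluded unless `include_within` is set.
#'
#' @param correlations A [pairwise_spearman()] result (or a list with
#'   `rho` and `q` matrices).
#' @param annotation data.frame with columns `compound`, `class`, covering
#'   every compound in the correlation matrices.
#' @param alpha Significance level on adjusted p-values (default 0.05).
#' @param include_within Also report within-class pairs (default FALSE).
#' @return A data.frame of class-pair results: `class_a`, `class_b`,
#'   `n_pairs`, `mean_rho`, `frac_significant`, `consistent`, `sign`.
#' @export
class_consistency <- function(correlations, annotation, alpha = 0.05,
                              include_within = FALSE) {
  rho <- correlations$rho
  q <- correlations$q
  ids <- colnames(rho)
  missing <- setdiff(ids, annotation$compound)
  if (length(missing)) {
    stop("annotation does not cover compounds: ",
         paste(head(missing, 5), collapse = ", "))
  }
  cls <- setNames(annotation$class, annotation$compound)[ids]
  classes <- sort(unique(cls))
  out <- list()
  idx <- if (include_within) {
    cbind(rep(seq_along(classes), each = length(classes)),
          rep(seq_along(classes), length(classes)))
  } else {
    t(combn(seq_along(classes), 2))
  }
  idx <- idx[idx[, 1] <= idx[, 2], , drop = FALSE]
  for (k in seq_len(nrow(idx))) {
    a <- classes[idx[k, 1]]
    b <- classes[idx[k, 2]]
    da <- ids[cls == a]
    db <- ids[cls == b]
    if (a == b) {
      if (length(da) < 2) next
      pr <- t(combn(da, 2))
    } else {
      pr <- expand.grid(da, db, stringsAsFactors = FALSE)
    }
    rr <- rho[cbind(match(pr[, 1], ids), match(pr[, 2], ids))]
    qq <- q[cbind(match(pr[, 1], ids), match(pr[, 2], ids))]
    if (!length(rr)) next
    consistent <- !anyNA(rr) && (all(rr > 0) || all(rr < 0))
    sign <- if (!consistent) "none" else if (all(rr > 0)) "positive" else
      "negative"
    out[[length(out) + 1L]] <- data.frame(
      class_a = a, class_b = b, n_pairs = length(rr),
      mean_rho = mean(rr, na.rm = TRUE),
      frac_significant = mean(!is.na(qq) & qq < alpha),
      consistent = consistent, sign = sign,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
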