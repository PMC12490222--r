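# Independent brute-force oracles. These deliberately avoid the package's
# implementation paths (and stats::cor / stats::wilcox.test): ranks, test
# statistics and adjustments are computed from first principles.

# average ranks by hand
oracle_rank <- function(x) {
  r <- numeric(length(x))
  for (i in seq_along(x)) {
    r[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }
  r
}

# Spearman rho as Pearson correlation of average ranks, by the explicit
# moment formula
oracle_spearman_rho <- function(x, y) {
  rx <- oracle_rank(x)
  ry <- oracle_rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# literal permutation generator (insertion construction, independent of
# the package's recursive-prefix construction); memoised per n
.oracle_perm_env <- new.env(parent = emptyenv())
oracle_perms <- function(n) {
  key <- as.character(n)
  if (!is.null(.oracle_perm_env[[key]])) return(.oracle_perm_env[[key]])
  p <- matrix(1L, 1, 1)
  for (m in 2:n) {
    rows <- vector("list", m)
    for (pos in seq_len(m)) {
      left <- if (pos > 1) p[, seq_len(pos - 1), drop = FALSE] else NULL
      right <- if (pos <= m - 1) p[, pos:(m - 1), drop = FALSE] else NULL
      rows[[pos]] <- cbind(left, m, right)
    }
    p <- do.call(rbind, rows)
  }
  .oracle_perm_env[[key]] <- p
  p
}

# two-sided Spearman p: full enumeration below n = 10 (tie-free),
# t-approximation at n >= 10
oracle_spearman_p <- function(x, y) {
  n <- length(x)
  rho <- oracle_spearman_rho(x, y)
  if (n <= 9) {
    rx <- oracle_rank(x)
    ry <- oracle_rank(y)
    perms <- oracle_perms(n)
    ry_perm <- matrix(ry[perms], nrow(perms))
    cx <- rx - mean(rx)
    num <- as.numeric(ry_perm %*% cx)
    den <- sqrt(sum(cx^2) * sum((ry - mean(ry))^2))
    r_all <- num / den
    return(mean(abs(r_all) >= abs(rho) - 1e-12))
  }
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(tstat), n - 2)
}

# Benjamini-Hochberg step-up by hand
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (k in rev(seq_len(m))) {
    val <- min(prev, p[o[k]] * m / k)
    adj[o[k]] <- val
    prev <- val
  }
  adj
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments
oracle_mw_p <- function(g1, g2) {
  pooled <- c(g1, g2)
  n1 <- length(g1)
  r <- oracle_rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  u_all <- apply(combs, 2, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  p_low <- mean(u_all <= u_obs + 1e-12)
  p_high <- mean(u_all >= u_obs - 1e-12)
  min(1, 2 * min(p_low, p_high))
}

# per-row variance by the definition, for the region-selection oracle
oracle_row_vars <- function(m) {
  apply(m, 1, function(v) sum((v - mean(v))^2) / (length(v) - 1))
}
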