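#' Derive a named per-stage random seed from one master seed
#'
#' All randomness in the package flows from a single integer master seed.
#' Each simulation or analysis stage draws its own seed through a named
#' stream so that stages can be regenerated independently of each other.
#'
#' @param seed Integer master seed.
#' @param stream Character stream name (e.g. `"layout"`, `"truth"`,
#'   `"cells"`, `"regions"`).
#' @return An integer seed strictly below 2^31.
#' @export
stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, length(stream) == 1L)
  codes <- utf8ToInt(as.character(stream))
  h <- 0
  for (ch in codes) h <- (h * 131 + ch) %% 1009
  as.integer((abs(as.numeric(seed)) * 1117 + h * 271 + 17) %% 2147483629)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Dirichlet draw (one vector per row of alpha recycling not needed here).
rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(x == 0)) x[which.max(alpha)] <- 1
  x / sum(x)
}

# Fractional Hill effect in [0, 1] at concentration `conc` (molar):
# 1 / (1 + 10^(slope * (log10(ec50) - log10(conc)))). Multiplied by the
# maximal kill fraction this gives the expected kill at `conc`.
hill_effect <- function(conc, ec50, slope) {
  1 / (1 + 10^(slope * (log10(ec50) - log10(conc))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
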