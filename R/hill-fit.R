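#' Fit a 3-parameter dose-response (Hill) model
#'
#' Least-squares fit of
#' `y = bottom + (1 - bottom) / (1 + 10^(slope * (x - logEC50)))`
#' with the top fixed at 1 (values are control-normalized) and
#' `x = log10(concentration)`. Initialization is deterministic: bottom at
#' the minimum observed value, logEC50 at the median log concentration,
#' slope 1; the Levenberg-Marquardt optimizer then refines the parameters
#' within bounds.
#'
#' @param series A dose-series data.frame (`concentration`, `value`) with
#'   at least 3 distinct concentrations.
#' @param fit_config Optional list: `maxiter` (default 200),
#'   `degenerate_span` (response span below which the fit is flagged
#'   degenerate, default 0.05).
#' @return An object of class `hill_fit` with components `coefficients`
#'   (`bottom`, `log_ec50`, `slope`), `fitted`, `residuals`, `converged`,
#'   `degenerate` and `data`.
#' @export
fit_dose_response_3p <- function(series, fit_config = list()) {
  maxiter <- fit_config$maxiter %||% 200
  degenerate_span <- fit_config$degenerate_span %||% 0.05
  df <- as.data.frame(series)
  concs <- unique(df$concentration)
  if (length(concs) < 3) stop("at least 3 concentrations are required")
  x <- log10(df$concentration)
  y <- df$value

  degenerate <- (max(y) - min(y)) < degenerate_span
  start <- list(bottom = min(y), log_ec50 = median(x), slope = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bottom + (1 - bottom) / (1 + 10^(slope * (x - log_ec50))),
      data = data.frame(x = x, y = y),
      start = start,
      lower = c(bottom = -0.5, log_ec50 = min(x) - 2, slope = 0.05),
      upper = c(bottom = 1.5, log_ec50 = max(x) + 2, slope = 20),
      control = minpack.lm::nls.lm.control(maxiter = maxiter)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(structure(list(
      coefficients = c(bottom = NA_real_, log_ec50 = NA_real_,
                       slope = NA_real_),
      fitted = rep(NA_real_, length(y)), residuals = rep(NA_real_, length(y)),
      converged = FALSE, degenerate = degenerate,
      data = data.frame(log10_concentration = x, value = y)
    ), class = "hill_fit"))
  }
  cf <- coef(fit)
  structure(list(
    coefficients = c(bottom = unname(cf["bottom"]),
                     log_ec50 = unname(cf["log_ec50"]),
                     slope = unname(cf["slope"])),
    fitted = as.numeric(fitted(fit)),
    residuals = as.numeric(residuals(fit)),
    converged = fit$convInfo$isConv %||% TRUE,
    degenerate = degenerate,
    data = data.frame(log10_concentration = x, value = y)
  ), class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("3-parameter dose-response fit (top fixed at 1)\n")
  if (x$degenerate) cat("  [degenerate: no appreciable response]\n")
  if (!x$converged) cat("  [did not converge; parameters absent]\n")
  cat(sprintf("  bottom = %.4f, EC50 = %.3g M, slope = %.3f\n",
              x$coefficients["bottom"], 10^x$coefficients["log_ec50"],
              x$coefficients["slope"]))
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...) object$coefficients

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  cf <- object$coefficients
  x <- if (is.null(newdata)) {
    object$data$log10_concentration
  } else if (is.data.frame(newdata)) {
    log10(newdata$concentration)
  } else {
    log10(as.numeric(newdata))
  }
  cf["bottom"] + (1 - cf["bottom"]) /
    (1 + 10^(cf["slope"] * (x - cf["log_ec50"])))
}

#' @export
residuals.hill_fit <- function(object, ...) object$residuals

#' @export
plot.hill_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$log10_concentration, d$value,
                 xlab = "log10 concentration (M)",
                 ylab = "normalized response", ylim = range(c(d$value, 0, 1)),
                 ...)
  if (x$converged && !anyNA(x$coefficients)) {
    xs <- seq(min(d$log10_concentration), max(d$log10_concentration),
              length.out = 100)
    graphics::lines(xs, predict(x, 10^xs))
  }
  invisible(x)
}
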