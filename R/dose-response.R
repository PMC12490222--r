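#' Filter treated wells with outlying total cell counts
#'
#' Removes treated wells whose total cell number exceeds the DMSO-control
#' mean by more than `n_sd` control standard deviations. The rule is
#' one-sided: only unusually high counts (doublets, debris, staining
#' artifacts) are removed; low counts are informative killing.
#'
#' @param well_summaries Treated [summarize_wells()] rows.
#' @param control_summaries DMSO control rows (at least 2).
#' @param n_sd SD multiple (default 4).
#' @return The kept treated well summaries, with the removed rows
#'   recorded in attribute `removed`.
#' @export
filter_cellcount_outliers <- function(well_summaries, control_summaries,
                                      n_sd = 4) {
  if (nrow(control_summaries) < 2) {
    stop("at least 2 control wells are required")
  }
  mu <- mean(control_summaries$n_total)
  s <- sd(control_summaries$n_total)
  cut <- mu + n_sd * s
  drop <- well_summaries$n_total > cut
  out <- well_summaries[!drop, , drop = FALSE]
  attr(out, "removed") <- well_summaries[drop, , drop = FALSE]
  attr(out, "cellcount_cut") <- cut
  out
}

#' Relative blast fraction of treated wells
#'
#' RBF = viable blast fraction in a treated well divided by the mean
#' viable blast fraction across negative (DMSO) control wells. 1 means no
#' on-target effect; values above 1 are possible and are not capped.
#'
#' @param well_summary Treated well summaries (any number of rows).
#' @param control_summaries DMSO control summaries.
#' @return Numeric vector of RBF values, one per treated row.
#' @export
compute_rbf <- function(well_summary, control_summaries) {
  ctrl <- mean(control_summaries$viable_blast_fraction, na.rm = TRUE)
  if (!is.finite(ctrl) || ctrl <= 0) {
    stop("control mean viable blast fraction is zero; sample unusable for relative scoring")
  }
  well_summary$viable_blast_fraction / ctrl
}

#' Build a dose-response series for one sample and compound
#'
#' @param well_summaries Treated well summaries for one sample.
#' @param control_summaries DMSO control summaries for the same sample.
#' @param compound Compound id to extract.
#' @param value_kind `"relative-blast-fraction"` (RBF; default) or
#'   `"absolute-normalized"` (viable blast counts over the control mean
#'   count, i.e. the Blast-AUC input).
#' @return A data.frame of class `dose_series` with columns
#'   `concentration`, `replicate`, `value` and attributes `sample_id`,
#'   `compound`, `value_kind`.
#' @export
build_dose_series <- function(well_summaries, control_summaries, compound,
                              value_kind = c("relative-blast-fraction",
                                             "absolute-normalized")) {
  value_kind <- match.arg(value_kind)
  rows <- well_summaries[well_summaries$treatment == compound, , drop = FALSE]
  value <- if (value_kind == "relative-blast-fraction") {
    compute_rbf(rows, control_summaries)
  } else {
    ctrl <- mean(control_summaries$n_viable_blast)
    if (!is.finite(ctrl) || ctrl <= 0) {
      stop("control mean viable blast count is zero")
    }
    rows$n_viable_blast / ctrl
  }
  out <- data.frame(
    concentration = rows$concentration_molar,
    replicate = rows$replicate,
    value = value
  )
  out <- out[order(out$concentration, out$replicate), , drop = FALSE]
  out <- out[!is.na(out$value), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, sample_id = unique(rows$sample_id)[1], compound = compound,
            value_kind = value_kind,
            class = c("dose_series", "data.frame"))
}

#' Filter a dose-response series for replicate outliers
#'
#' Two rules, applied in order and iterated to a fixpoint so the filter is
#' idempotent. Rule A walks concentrations in ascending order and drops
#' any replicate value more than 50% above the running (already filtered)
#' average of the previous retained concentration. Rule B drops whole
#' concentrations whose replicates differ by more than 50% of their mean;
#' single-replicate concentrations are exempt.
#'
#' @param series A [build_dose_series()] data.frame (or any data.frame
#'   with `concentration`, `replicate`, `value`).
#' @param rise_factor Rule-A multiplier (default 1.5).
#' @param replicate_tol Rule-B relative-difference bound (default 0.5).
#' @return The filtered series; attribute `dropped` records removed rows
#'   with reasons, attribute `unusable` is `TRUE` when filtering emptied
#'   the series.
#' @export
filter_dose_response <- function(series, rise_factor = 1.5,
                                 replicate_tol = 0.5) {
  cur <- as.data.frame(series)
  dropped <- cur[0, , drop = FALSE]
  dropped$reason <- character(0)
  repeat {
    changed <- FALSE
    ## rule A: ascending concentrations, running filtered average
    concs <- sort(unique(cur$concentration))
    prev_avg <- NA_real_
    keep <- rep(TRUE, nrow(cur))
    for (cc in concs) {
      at <- which(cur$concentration == cc)
      if (!is.na(prev_avg)) {
        bad <- at[cur$value[at] > rise_factor * prev_avg]
        keep[bad] <- FALSE
        at <- setdiff(at, bad)
      }
      if (length(at)) prev_avg <- mean(cur$value[at])
    }
    if (any(!keep)) {
      d <- cur[!keep, , drop = FALSE]
      d$reason <- "rise-above-previous-concentration"
      dropped <- rbind(dropped, d)
      cur <- cur[keep, , drop = FALSE]
      changed <- TRUE
    }
    ## rule B: replicate disagreement per concentration
    keep <- rep(TRUE, nrow(cur))
    for (cc in unique(cur$concentration)) {
      at <- which(cur$concentration == cc)
      if (length(at) < 2) next
      v <- cur$value[at]
      m <- mean(v)
      if (m > 0 && (max(v) - min(v)) / m > replicate_tol) keep[at] <- FALSE
    }
    if (any(!keep)) {
      d <- cur[!keep, , drop = FALSE]
      d$reason <- "replicate-disagreement"
      dropped <- rbind(dropped, d)
      cur <- cur[keep, , drop = FALSE]
      changed <- TRUE
    }
    if (!changed) break
  }
  rownames(cur) <- NULL
  attrs <- attributes(series)
  for (a in c("sample_id", "compound", "value_kind")) {
    attr(cur, a) <- attrs[[a]]
  }
  class(cur) <- c("dose_series", "data.frame")
  attr(cur, "dropped") <- dropped
  attr(cur, "unusable") <- nrow(cur) == 0
  if (nrow(cur) == 0) attr(cur, "reason") <- "all values removed by filtering"
  cur
}

#' Interpolate per-concentration averages onto a target grid
#'
#' Linear interpolation of the per-concentration average values on the
#' log10-concentration axis. Points already on the grid are unchanged; the
#' target grid must lie within the measured concentration range
#' (no extrapolation).
#'
#' @param series A dose-series data.frame.
#' @param target_concentrations Ascending molar target grid.
#' @return A `dose_series` on the target grid (one averaged value per
#'   concentration).
#' @export
interpolate_series <- function(series, target_concentrations) {
  concs <- sort(unique(series$concentration))
  if (length(concs) < 2) stop("at least 2 measured concentrations required")
  rng <- range(concs)
  if (any(target_concentrations < rng[1] * (1 - 1e-9)) ||
      any(target_concentrations > rng[2] * (1 + 1e-9))) {
    stop("target grid outside the measured concentration range; extrapolation is not supported")
  }
  avg <- vapply(concs, function(cc) {
    mean(series$value[series$concentration == cc])
  }, numeric(1))
  fit <- approx(log10(concs), avg, xout = log10(target_concentrations),
                rule = 1)
  out <- data.frame(
    concentration = target_concentrations,
    replicate = 1L,
    value = fit$y
  )
  attrs <- attributes(series)
  structure(out, sample_id = attrs$sample_id, compound = attrs$compound,
            value_kind = attrs$value_kind,
            class = c("dose_series", "data.frame"))
}

#' Area-under-curve inhibition score of a dose-response series
#'
#' Averages replicate values per concentration, integrates the averages
#' with the trapezoid rule over a unit-normalized axis, and returns
#' `1 - AUC` so that higher scores mean stronger inhibition. A flat series
#' at 1 (no effect) scores 0; a flat series at 0 (complete kill) scores 1;
#' resistant samples (values above 1) can score negative. Applied to
#' relative blast fractions this is the RBF-AUC score; applied to
#' control-normalized absolute viable-blast counts it is the Blast AUC.
#'
#' @param series A dose-series data.frame.
#' @param axis `"index"` (default; equally spaced concentration indices
#'   mapped to `[0, 1]`) or `"log10"` (log-molar axis normalized to
#'   `[0, 1]`).
#' @return The inhibition score, or `NA` with attribute `reason` when the
#'   series has fewer than 2 retained concentrations.
#' @export
auc_score <- function(series, axis = c("index", "log10")) {
  axis <- match.arg(axis)
  concs <- sort(unique(series$concentration))
  if (length(concs) < 2) {
    return(structure(NA_real_, reason = "fewer than 2 concentrations"))
  }
  y <- vapply(concs, function(cc) {
    mean(series$value[series$concentration == cc])
  }, numeric(1))
  x <- if (axis == "index") {
    seq(0, 1, length.out = length(concs))
  } else {
    lx <- log10(concs)
    (lx - lx[1]) / (lx[length(lx)] - lx[1])
  }
  auc <- sum(diff(x) * (head(y, -1) + y[-1]) / 2)
  1 - auc
}

#' Score a full cohort into a sensitivity matrix
#'
#' Runs the complete scoring chain for every sample and compound: total
#' cell-count outlier filtering against the sample's DMSO controls,
#' RBF (or control-normalized absolute count) computation, the two
#' dose-response outlier rules, and the trapezoidal `1 - AUC` score.
#'
#' @param well_summaries A [simulate_well_summaries()] /
#'   [summarize_wells()] table covering one or more samples (DMSO control
#'   rows included).
#' @param score_kind `"rbf-auc"` (default) or `"blast-auc"`.
#' @param axis Integration axis passed to [auc_score()].
#' @return A samples x compounds matrix of class `sensitivity_matrix`
#'   with attributes `score_kind` and `missing_reasons`.
#' @export
score_cohort <- function(well_summaries, score_kind = c("rbf-auc",
                                                        "blast-auc"),
                         axis = "index") {
  score_kind <- match.arg(score_kind)
  value_kind <- if (score_kind == "rbf-auc") "relative-blast-fraction" else
    "absolute-normalized"
  samples <- unique(well_summaries$sample_id)
  compounds <- setdiff(unique(well_summaries$treatment), "DMSO")
  mat <- matrix(NA_real_, length(samples), length(compounds),
                dimnames = list(samples, compounds))
  reasons <- list()
  for (s in samples) {
    ws <- well_summaries[well_summaries$sample_id %in% s, , drop = FALSE]
    ctrl <- ws[ws$treatment == "DMSO" & !ws$flagged, , drop = FALSE]
    treated <- ws[ws$treatment != "DMSO", , drop = FALSE]
    treated <- filter_cellcount_outliers(treated, ctrl)
    treated <- treated[!treated$flagged, , drop = FALSE]
    cmp_rows <- split(seq_len(nrow(treated)), treated$treatment)
    for (cmp in compounds) {
      rows <- treated[cmp_rows[[cmp]], , drop = FALSE]
      res <- tryCatch({
        ser <- build_dose_series(rows, ctrl, cmp, value_kind = value_kind)
        ser <- filter_dose_response(ser)
        auc_score(ser, axis = axis)
      }, error = function(e) structure(NA_real_, reason = conditionMessage(e)))
      mat[s, cmp] <- as.numeric(res)
      if (is.na(mat[s, cmp])) {
        reasons[[paste(s, cmp, sep = ":")]] <-
          attr(res, "reason") %||% "unscorable"
      }
    }
  }
  structure(mat, score_kind = score_kind, missing_reasons = reasons,
            class = c("sensitivity_matrix", "matrix", "array"))
}

#' Z-scale a sensitivity matrix per compound
#'
#' Centers and scales each compound column to mean 0 and population
#' standard deviation 1 (divide by n) over its non-missing entries, the
#' convention used for cohort-level depictions. Missing entries stay
#' missing; constant columns are set to 0 and flagged.
#'
#' @param matrix A samples x compounds matrix.
#' @return The scaled matrix with attributes `score_kind =
#'   "scaled-<input>"` and `constant_columns`.
#' @export
scale_matrix <- function(matrix) {
  m <- as.matrix(matrix)
  constant <- character(0)
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    ok <- !is.na(v)
    if (sum(ok) < 2) {
      stop("at least 2 non-missing values per compound column are required (",
           colnames(m)[j] %||% j, ")")
    }
    mu <- mean(v[ok])
    s <- sqrt(mean((v[ok] - mu)^2))  # population SD
    if (s == 0) {
      m[ok, j] <- 0
      constant <- c(constant, colnames(m)[j] %||% as.character(j))
    } else {
      m[ok, j] <- (v[ok] - mu) / s
    }
  }
  structure(m,
            score_kind = paste0("scaled-",
                                attr(matrix, "score_kind") %||% "score"),
            constant_columns = constant,
            class = c("sensitivity_matrix", "matrix", "array"))
}
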