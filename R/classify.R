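#' Classify cells into blast, T and other by marker-intensity gating
#'
#' Default pluggable cell-type classifier: each marker channel gets an
#' intensity gate (a fixed threshold or `"auto"`, which fits a
#' two-component Gaussian mixture to the log10 intensities and places the
#' gate at the equal-density boundary between the components). A cell is
#' a T cell when any T-marker channel exceeds its gate; a blast when any
#' blast-marker channel exceeds its gate and no T-marker does; `other`
#' otherwise. Given the gates the assignment is deterministic, so a
#' learned classifier honouring the same contract can be plugged in.
#'
#' @param cell_table Per-cell table with the panel's channel columns.
#' @param marker_panel data.frame with columns `channel` and `role`
#'   (`"blast"` or `"T"`); default CD34 = blast marker, CD3 = T marker.
#' @param gating_config Named list channel -> numeric gate or `"auto"`
#'   (default auto for all panel channels).
#' @return A character vector of classes (`blast`/`T`/`other`) with the
#'   gates used attached as attribute `gates`.
#' @export
classify_cells <- function(cell_table,
                           marker_panel = data.frame(
                             channel = c("CD34", "CD3"),
                             role = c("blast", "T"),
                             stringsAsFactors = FALSE),
                           gating_config = list()) {
  stopifnot(all(c("channel", "role") %in% names(marker_panel)),
            all(marker_panel$role %in% c("blast", "T")))
  absent <- setdiff(marker_panel$channel, names(cell_table))
  if (length(absent)) {
    stop("marker panel names channels absent from the table: ",
         paste(absent, collapse = ", "))
  }
  gates <- numeric(0)
  for (ch in marker_panel$channel) {
    g <- gating_config[[ch]] %||% "auto"
    if (identical(g, "auto")) {
      g <- .auto_gate(cell_table[[ch]])
    }
    gates[ch] <- g
  }
  above <- vapply(marker_panel$channel,
                  function(ch) cell_table[[ch]] > gates[ch],
                  logical(nrow(cell_table)))
  if (nrow(cell_table) == 1L) above <- matrix(above, nrow = 1)
  t_ch <- marker_panel$role == "T"
  any_t <- if (any(t_ch)) rowSums(above[, t_ch, drop = FALSE]) > 0 else FALSE
  any_b <- if (any(!t_ch)) rowSums(above[, !t_ch, drop = FALSE]) > 0 else FALSE
  cls <- rep("other", nrow(cell_table))
  cls[any_b & !any_t] <- "blast"
  cls[any_t] <- "T"
  attr(cls, "gates") <- gates
  cls
}

# Equal-density boundary between the two components of a univariate
# two-component Gaussian mixture fit to log10 intensities; gate returned
# on the intensity scale.
.auto_gate <- function(x) {
  lx <- log10(pmax(x, .Machine$double.eps))
  fit <- .fit_gmm2(lx)
  if (is.null(fit)) return(10^median(lx))
  mu <- fit$mean
  sdv <- fit$sd
  pro <- fit$pro
  lo <- min(mu)
  hi <- max(mu)
  o <- order(mu)
  f <- function(z) {
    pro[o[1]] * dnorm(z, mu[o[1]], sdv[o[1]]) -
      pro[o[2]] * dnorm(z, mu[o[2]], sdv[o[2]])
  }
  gate <- tryCatch(stats::uniroot(f, c(lo, hi))$root,
                   error = function(e) (lo + hi) / 2)
  10^gate
}

#' Summarize wells into viable-cell tallies
#'
#' Counts, per well, total cells and viable cells by class, and derives
#' the viable blast fraction that feeds dose-response scoring. Cells with
#' viability label `unlabeled` are handled per `unlabeled_policy`: the
#' default excludes them from both the viable numerator and denominator
#' (they still count toward `n_total`); `"nonviable"` treats them as
#' nonviable (identical tallies, stated explicitly). Wells with zero
#' viable cells are flagged; their relative blast fraction is undefined.
#'
#' @param cell_table Per-cell table (one row per cell).
#' @param viability_labels A [label_viability()] result or a character
#'   vector aligned with `cell_table` rows.
#' @param cell_classes A [classify_cells()] result or aligned character
#'   vector (`blast`/`T`/`other`).
#' @param unlabeled_policy `"exclude"` (default) or `"nonviable"`.
#' @return A data.frame of class `well_summary`, one row per well.
#' @export
summarize_wells <- function(cell_table, viability_labels, cell_classes,
                            unlabeled_policy = c("exclude", "nonviable")) {
  unlabeled_policy <- match.arg(unlabeled_policy)
  labels <- if (inherits(viability_labels, "viability_labels")) {
    viability_labels$label
  } else {
    viability_labels
  }
  classes <- as.character(cell_classes)
  if (length(labels) != nrow(cell_table) ||
      length(classes) != nrow(cell_table)) {
    stop("labels and classes must align with the cell table rows")
  }
  viable <- labels == "viable"
  key <- paste(cell_table$sample_id %||% "", cell_table$plate_id %||% "",
               cell_table$well_id, sep = "\r")
  ukey <- unique(key)
  idx <- match(key, ukey)
  tab <- function(mask) {
    tabulate(idx[mask], nbins = length(ukey))
  }
  first <- match(ukey, key)
  out <- data.frame(
    sample_id = (cell_table$sample_id %||% NA_character_)[first],
    plate_id = (cell_table$plate_id %||% NA_character_)[first],
    well_id = cell_table$well_id[first],
    treatment = (cell_table$treatment %||% NA_character_)[first],
    concentration_molar = (cell_table$concentration_molar %||% NA_real_)[first],
    replicate = (cell_table$replicate %||% NA_integer_)[first],
    n_total = tab(rep(TRUE, length(key))),
    n_viable = tab(viable),
    n_viable_blast = tab(viable & classes == "blast"),
    n_viable_T = tab(viable & classes == "T"),
    n_viable_other = tab(viable & classes == "other"),
    stringsAsFactors = FALSE
  )
  out$viable_blast_fraction <- ifelse(out$n_viable > 0,
                                      out$n_viable_blast / out$n_viable,
                                      NA_real_)
  out$flagged <- out$n_viable == 0
  for (ch in intersect(c("dye_intensity", "CD34", "CD3"), names(cell_table))) {
    out[[paste0("mean_", ch)]] <- as.numeric(
      tapply(cell_table[[ch]], factor(idx, levels = seq_along(ukey)), mean))
  }
  rownames(out) <- NULL
  class(out) <- c("well_summary", "data.frame")
  out
}
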