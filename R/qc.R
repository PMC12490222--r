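#' Exclude wells with outlying channel intensities
#'
#' A well is excluded when, for at least one imaged channel, the absolute
#' difference between its mean intensity and the grand mean of well means
#' is at least `n_sd` standard deviations of the well means (two-sided).
#' Channels whose well means have zero spread contribute no exclusions.
#'
#' @param cell_table Per-cell table with a `well_id` column.
#' @param channels Channel columns to screen; defaults to the viability
#'   dye and any marker intensity columns present.
#' @param n_sd SD multiple for the cut (default 4).
#' @return A list with `cells` (the kept table) and `report` (a
#'   `qc_report` recording excluded wells with their primary reason and
#'   the thresholds used).
#' @export
qc_wells <- function(cell_table, channels = NULL, n_sd = 4) {
  if (nrow(cell_table) == 0) stop("cell table is empty")
  channels <- channels %||%
    intersect(c("dye_intensity", "CD34", "CD3", "intensity_mean"),
              names(cell_table))
  if (!length(channels)) stop("no channel columns found")
  wells <- unique(cell_table$well_id)
  if (length(wells) < 2) {
    stop("at least 2 wells are required to estimate well-mean spread")
  }
  key <- interaction(cell_table$plate_id %||% "", cell_table$well_id,
                     drop = TRUE)
  well_means <- do.call(cbind, lapply(channels, function(ch) {
    tapply(cell_table[[ch]], key, mean)
  }))
  colnames(well_means) <- channels

  excluded <- character(0)
  reason_channel <- character(0)
  thresholds <- list()
  for (ch in channels) {
    m <- well_means[, ch]
    mu <- mean(m)
    s <- sd(m)
    thresholds[[ch]] <- c(mean = mu, sd = s, cut = n_sd)
    if (is.na(s) || s == 0) next
    out <- names(m)[abs(m - mu) >= n_sd * s]
    new <- setdiff(out, excluded)
    excluded <- c(excluded, new)
    reason_channel <- c(reason_channel, rep(ch, length(new)))
  }
  drop <- key %in% excluded
  report <- structure(list(
    excluded_wells = data.frame(
      well_key = excluded,
      reason = rep("channel-intensity-outlier", length(excluded)),
      channel = reason_channel, stringsAsFactors = FALSE
    ),
    excluded_cells = data.frame(reason = character(0), n = integer(0)),
    thresholds = thresholds,
    n_in = nrow(cell_table), n_kept = sum(!drop), n_excluded = sum(drop)
  ), class = "qc_report")
  list(cells = cell_table[!drop, , drop = FALSE], report = report)
}

#' Exclude cells outside declared morphology-descriptor intervals
#'
#' Removes segmentation artifacts and mis-segmented cells by thresholding
#' on morphology descriptors. A cell is removed when any declared
#' descriptor falls outside its `(min, max)` interval. An empty threshold
#' list is the identity.
#'
#' @param cell_table Per-cell table.
#' @param morphology_thresholds Named list mapping descriptor to
#'   `c(min, max)` (either bound may be `-Inf`/`Inf`).
#' @return A list with `cells` and a `qc_report`.
#' @export
qc_cells <- function(cell_table, morphology_thresholds = list()) {
  absent <- setdiff(names(morphology_thresholds), names(cell_table))
  if (length(absent)) {
    stop("threshold on descriptor absent from the table: ",
         paste(absent, collapse = ", "))
  }
  drop <- rep(FALSE, nrow(cell_table))
  for (d in names(morphology_thresholds)) {
    b <- morphology_thresholds[[d]]
    stopifnot(length(b) == 2)
    drop <- drop | cell_table[[d]] < b[1] | cell_table[[d]] > b[2]
  }
  report <- structure(list(
    excluded_wells = data.frame(well_key = character(0), reason = character(0),
                                channel = character(0),
                                stringsAsFactors = FALSE),
    excluded_cells = data.frame(reason = "morphology-threshold",
                                n = sum(drop), stringsAsFactors = FALSE),
    thresholds = morphology_thresholds,
    n_in = nrow(cell_table), n_kept = sum(!drop), n_excluded = sum(drop)
  ), class = "qc_report")
  list(cells = cell_table[!drop, , drop = FALSE], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d records in, %d kept, %d excluded\n",
              x$n_in, x$n_kept, x$n_excluded))
  if (nrow(x$excluded_wells)) {
    cat("  excluded wells:", nrow(x$excluded_wells),
        "(channel-intensity-outlier)\n")
  }
  if (nrow(x$excluded_cells) && sum(x$excluded_cells$n)) {
    cat("  excluded cells:", sum(x$excluded_cells$n),
        "(morphology-threshold)\n")
  }
  invisible(x)
}
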