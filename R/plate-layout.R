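#' Generate a randomized multi-plate screening layout
#'
#' Lays out `n_compounds` compounds at `n_concentrations` concentrations in
#' `n_replicates` technical replicates across `n_plates` plates of a given
#' well format, reserving `n_controls_per_plate` solvent (DMSO) control
#' wells on every plate. Treatment positions are a seeded random
#' permutation of the non-control wells, so re-running with the same seed
#' reproduces the layout exactly.
#'
#' Supported plate formats are 96 (8 x 12), 384 (16 x 24) and
#' 1536 (32 x 48) wells; well ids are row-major plate coordinates
#' ("A01".."P24" for the 384-well format).
#'
#' @param n_compounds Number of compounds (default 115).
#' @param n_concentrations Concentrations per compound (default 3).
#' @param n_replicates Replicate wells per compound/concentration
#'   (default 2).
#' @param n_controls_per_plate DMSO control wells on each plate
#'   (default 32).
#' @param n_plates Number of plates (default 2).
#' @param plate_format Wells per plate: 96, 384 or 1536 (default 384).
#' @param seed Integer randomization seed.
#' @param compounds Optional character vector of compound ids; defaults to
#'   the first `n_compounds` entries of [default_compound_library()].
#' @param concentrations Optional list/matrix of per-compound molar
#'   concentration grids; by default a geometric 10-fold series topping out
#'   at 10 uM (1e-5 M) is used for every compound.
#' @return A data.frame of class `plate_layout` with columns `plate_id`,
#'   `well_id`, `treatment` (compound id or `"DMSO"`),
#'   `concentration_molar` (`NA` for controls) and `replicate`.
#' @export
generate_plate_layout <- function(n_compounds = 115, n_concentrations = 3,
                                  n_replicates = 2, n_controls_per_plate = 32,
                                  n_plates = 2, plate_format = 384, seed = 1,
                                  compounds = NULL, concentrations = NULL) {
  geom <- list(`96` = c(8, 12), `384` = c(16, 24), `1536` = c(32, 48))
  key <- as.character(plate_format)
  if (!key %in% names(geom)) {
    stop("unsupported plate format: ", plate_format,
         " (supported: 96, 384, 1536)")
  }
  n_treated <- n_compounds * n_concentrations * n_replicates
  n_needed <- n_treated + n_plates * n_controls_per_plate
  n_avail <- n_plates * plate_format
  if (n_needed > n_avail) {
    stop(sprintf(
      "plate capacity exceeded: %d wells required (%d treated + %d controls) but only %d available",
      n_needed, n_treated, n_plates * n_controls_per_plate, n_avail
    ))
  }
  if (is.null(compounds)) {
    compounds <- head(default_compound_library()$compound, n_compounds)
  }
  stopifnot(length(compounds) == n_compounds)
  if (is.null(concentrations) && n_compounds > 0) {
    grid <- 1e-5 / 10^(seq(n_concentrations - 1, 0))
    concentrations <- matrix(rep(grid, each = n_compounds), nrow = n_compounds,
                             dimnames = list(compounds, NULL))
  }

  dims <- geom[[key]]
  wells <- as.vector(t(outer(LETTERS[seq_len(dims[1])],
                             sprintf("%02d", seq_len(dims[2])), paste0)))

  with_seed(seed, {
    slots <- data.frame(
      plate_id = rep(sprintf("P%d", seq_len(n_plates)), each = plate_format),
      well_id = rep(wells, n_plates),
      stringsAsFactors = FALSE
    )
    control_idx <- unlist(lapply(seq_len(n_plates), function(p) {
      offset <- (p - 1L) * plate_format
      offset + sample.int(plate_format, n_controls_per_plate)
    }))
    open_idx <- setdiff(seq_len(nrow(slots)), control_idx)
    treat_idx <- if (n_treated > 0) sample(open_idx, n_treated) else integer(0)

    layout <- slots[sort(control_idx), , drop = FALSE]
    layout$treatment <- "DMSO"
    layout$concentration_molar <- NA_real_
    layout$replicate <- NA_integer_

    if (n_treated > 0) {
      trt <- expand.grid(
        replicate = seq_len(n_replicates),
        conc_index = seq_len(n_concentrations),
        compound = compounds,
        stringsAsFactors = FALSE
      )
      trt$concentration_molar <- concentrations[
        cbind(match(trt$compound, compounds), trt$conc_index)]
      pos <- slots[treat_idx, , drop = FALSE]  # sampled order = permutation
      treated <- data.frame(
        plate_id = pos$plate_id,
        well_id = pos$well_id,
        treatment = trt$compound,
        concentration_molar = trt$concentration_molar,
        replicate = trt$replicate,
        stringsAsFactors = FALSE
      )
      layout <- rbind(layout, treated)
    }
    layout <- layout[order(layout$plate_id, layout$well_id), ]
    rownames(layout) <- NULL
    attr(layout, "randomization_seed") <- as.integer(seed)
    attr(layout, "plate_format") <- plate_format
    class(layout) <- c("plate_layout", "data.frame")
    layout
  })
}

#' @export
print.plate_layout <- function(x, ...) {
  n_ctrl <- sum(x$treatment == "DMSO")
  n_trt <- nrow(x) - n_ctrl
  cat(sprintf(
    "<plate_layout> %d plates (%d-well), %d treated wells, %d control wells, %d compounds\n",
    length(unique(x$plate_id)), attr(x, "plate_format"), n_trt, n_ctrl,
    length(setdiff(unique(x$treatment), "DMSO"))
  ))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}
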