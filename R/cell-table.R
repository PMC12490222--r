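#' Configuration for the single-cell assay simulator
#'
#' Declares the seeding density, plating efficiency, baseline population
#' composition and viability, the class-conditional morphology and marker
#' intensity distributions, and the viability-dye intensity model. Dye and
#' marker intensities are lognormal (positive, bimodal across the
#' viable/nonviable and marker-positive/negative modes); morphology
#' features are class-conditional Gaussians. With the defaults the two dye
#' modes sit 10 component-SDs apart on the log scale and marker modes
#' roughly 8.5 SDs apart, matching what the semi-supervised labeling
#' procedure assumes.
#'
#' @param seeding_density Cells seeded per well (default 9000).
#' @param plating_efficiency Fraction of seeded cells recovered as
#'   segmented cells (default 0.7).
#' @param blast_fraction,t_fraction Baseline class composition (remainder
#'   is "other").
#' @param baseline_viability Viable fraction in untreated wells.
#' @param dye_meanlog Named log-scale means of the viability dye for
#'   viable and nonviable cells.
#' @param dye_sdlog Log-scale SD of the dye intensity.
#' @param marker_meanlog Named log-scale means for marker-positive and
#'   marker-negative cells.
#' @param marker_sdlog Log-scale SD of marker intensities.
#' @param morphology_means 3 x 6 matrix of class-conditional morphology
#'   means (rows blast/T/other).
#' @param morphology_sd Morphology feature SD.
#' @param artifact_rate Fraction of cells injected as extreme-area
#'   segmentation artifacts (latent flag recorded; default 0).
#' @return A list of class `assay_config`.
#' @export
assay_config <- function(seeding_density = 9000, plating_efficiency = 0.7,
                         blast_fraction = 0.6, t_fraction = 0.15,
                         baseline_viability = 0.8,
                         dye_meanlog = c(viable = log(150),
                                         nonviable = log(3000)),
                         dye_sdlog = 0.3,
                         marker_meanlog = c(positive = log(2000),
                                            negative = log(100)),
                         marker_sdlog = 0.35,
                         morphology_means = NULL,
                         morphology_sd = 1,
                         artifact_rate = 0) {
  if (blast_fraction + t_fraction > 1) {
    stop("blast_fraction + t_fraction must not exceed 1")
  }
  if (is.null(morphology_means)) {
    morphology_means <- rbind(
      blast = c(area = 9, perimeter = 11, eccentricity = 0.45,
                intensity_mean = 6, texture_contrast = 3.0,
                texture_entropy = 4.5),
      T = c(area = 4, perimeter = 7, eccentricity = 0.2,
            intensity_mean = 4, texture_contrast = 1.5,
            texture_entropy = 2.5),
      other = c(area = 6.5, perimeter = 9, eccentricity = 0.6,
                intensity_mean = 5, texture_contrast = 2.2,
                texture_entropy = 3.5)
    )
  }
  structure(list(
    seeding_density = seeding_density,
    plating_efficiency = plating_efficiency,
    blast_fraction = blast_fraction, t_fraction = t_fraction,
    baseline_viability = baseline_viability,
    dye_meanlog = dye_meanlog, dye_sdlog = dye_sdlog,
    marker_meanlog = marker_meanlog, marker_sdlog = marker_sdlog,
    morphology_means = morphology_means, morphology_sd = morphology_sd,
    artifact_rate = artifact_rate
  ), class = "assay_config")
}

#' Names of the morphology descriptor columns in simulated cell tables
#' @return Character vector of the six morphology feature names.
#' @export
morphology_features <- function() {
  c("area", "perimeter", "eccentricity", "intensity_mean",
    "texture_contrast", "texture_entropy")
}

# Expected survival multipliers for one sample/well treatment.
# Blast survival follows the sample's Hill curve; non-blast cells are
# affected through the compound's off-target kill with the same curve
# shape; DMSO control wells are unaffected.
.well_survival <- function(truth, sample_id, treatment, conc) {
  if (treatment == "DMSO" || is.na(conc)) {
    return(c(blast = 1, T = 1, other = 1))
  }
  mk <- truth$maxkill[sample_id, treatment]
  shape <- hill_effect(conc, truth$ec50[sample_id, treatment],
                       truth$slope[sample_id, treatment])
  off <- truth$offtarget[[treatment]]
  c(blast = 1 - mk * shape, T = 1 - off * shape, other = 1 - off * shape)
}

# Draw per-well class/viability counts for one sample. Killed cells stay
# in the well as nonviable objects (fixable dyes stain dead cells; they do
# not vanish), so total counts are treatment-independent.
.simulate_well_counts <- function(layout, truth, sample_id, assay) {
  n_well <- nrow(layout)
  props <- c(blast = assay$blast_fraction, T = assay$t_fraction,
             other = 1 - assay$blast_fraction - assay$t_fraction)
  n_total <- rpois(n_well, assay$seeding_density * assay$plating_efficiency)
  counts <- matrix(0L, n_well, 3, dimnames = list(NULL, names(props)))
  viable <- matrix(0L, n_well, 3, dimnames = list(NULL, names(props)))
  for (w in seq_len(n_well)) {
    cls <- as.integer(rmultinom(1, n_total[w], props))
    counts[w, ] <- cls
    surv <- .well_survival(truth, sample_id, layout$treatment[w],
                           layout$concentration_molar[w])
    viable[w, ] <- rbinom(3, cls, assay$baseline_viability * pmin(pmax(surv, 0), 1))
  }
  list(n_total = n_total, counts = counts, viable = viable)
}

#' Simulate well-level summaries for cohort samples
#'
#' Draws the same well-level law as [simulate_cell_table()] (Poisson total
#' counts, multinomial class composition, binomial survival under each
#' sample's Hill curve) but emits per-well tallies directly, without
#' materialising individual cells. This makes full-cohort simulation
#' (45 samples x 768 wells x ~9,000 cells) tractable; marginally the
#' summaries are distributed identically to running [summarize_wells()]
#' on an error-free annotation of the per-cell table.
#'
#' @param layout A [generate_plate_layout()] result.
#' @param truth A [simulate_cohort_truth()] result.
#' @param assay An [assay_config()].
#' @param seed Integer seed.
#' @param samples Character vector of sample ids (default: all in `truth`).
#' @return A data.frame of class `well_summary` with one row per sample and
#'   well: ids, treatment metadata, `n_total`, `n_viable`,
#'   `n_viable_blast`, `n_viable_T`, `n_viable_other`,
#'   `viable_blast_fraction` and a `flagged` column for wells without
#'   viable cells.
#' @export
simulate_well_summaries <- function(layout, truth, assay = assay_config(),
                                    seed = 1, samples = NULL) {
  stopifnot(inherits(truth, "cohort_truth"))
  samples <- samples %||% truth$samples$sample_id
  missing <- setdiff(samples, truth$samples$sample_id)
  if (length(missing)) {
    stop("samples absent from cohort truth: ", paste(missing, collapse = ", "))
  }
  treated <- setdiff(unique(layout$treatment), "DMSO")
  unknown <- setdiff(treated, colnames(truth$maxkill))
  if (length(unknown)) {
    stop("layout compounds absent from cohort truth: ",
         paste(head(unknown, 5), collapse = ", "))
  }
  out <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    s <- samples[i]
    cw <- with_seed(stream_seed(seed, paste0("wells:", s)),
                    .simulate_well_counts(layout, truth, s, assay))
    n_viable <- as.integer(rowSums(cw$viable))
    df <- data.frame(
      sample_id = s, plate_id = layout$plate_id, well_id = layout$well_id,
      treatment = layout$treatment,
      concentration_molar = layout$concentration_molar,
      replicate = layout$replicate,
      n_total = cw$n_total, n_viable = n_viable,
      n_viable_blast = cw$viable[, "blast"],
      n_viable_T = cw$viable[, "T"],
      n_viable_other = cw$viable[, "other"],
      stringsAsFactors = FALSE
    )
    df$viable_blast_fraction <- ifelse(df$n_viable > 0,
                                       df$n_viable_blast / df$n_viable,
                                       NA_real_)
    df$flagged <- df$n_viable == 0
    out[[i]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("well_summary", "data.frame")
  res
}

#' Simulate a per-cell feature table
#'
#' Generates one record per segmented cell: well assignment, six
#' morphology descriptors (class-conditional Gaussians), a positive
#' viability-dye intensity (lognormal, bimodal between viable and
#' nonviable cells), marker intensities (`CD34` as the blast marker,
#' `CD3` as the T-cell marker), and the latent ground truth
#' (`latent_class`, `latent_viable`, `latent_artifact`) used by recovery
#' tests. Treated wells follow the sample's planted Hill curve; control
#' wells are unaffected by compound terms.
#'
#' @inheritParams simulate_well_summaries
#' @return A data.frame with one row per cell.
#' @export
simulate_cell_table <- function(layout, truth, assay = assay_config(),
                                seed = 1, samples = NULL) {
  stopifnot(inherits(truth, "cohort_truth"))
  samples <- samples %||% truth$samples$sample_id
  missing <- setdiff(samples, truth$samples$sample_id)
  if (length(missing)) {
    stop("samples absent from cohort truth: ", paste(missing, collapse = ", "))
  }
  feats <- morphology_features()
  out <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    s <- samples[i]
    out[[i]] <- with_seed(stream_seed(seed, paste0("cells:", s)), {
      cw <- .simulate_well_counts(layout, truth, s, assay)
      classes <- colnames(cw$counts)
      n_cells <- sum(cw$counts)
      well_idx <- rep(seq_len(nrow(layout)), times = rowSums(cw$counts))
      cls <- unlist(lapply(seq_len(nrow(layout)), function(w) {
        rep(classes, times = cw$counts[w, ])
      }), use.names = FALSE)
      viab <- unlist(lapply(seq_len(nrow(layout)), function(w) {
        unlist(lapply(seq_along(classes), function(k) {
          nk <- cw$counts[w, k]
          if (nk == 0) return(logical(0))
          sample(rep(c(TRUE, FALSE), c(cw$viable[w, k], nk - cw$viable[w, k])))
        }))
      }), use.names = FALSE)

      cls_idx <- match(cls, rownames(assay$morphology_means))
      morph <- assay$morphology_means[cls_idx, , drop = FALSE] +
        matrix(rnorm(n_cells * length(feats), 0, assay$morphology_sd),
               ncol = length(feats))
      colnames(morph) <- feats

      dye <- rlnorm(n_cells,
                    ifelse(viab, assay$dye_meanlog[["viable"]],
                           assay$dye_meanlog[["nonviable"]]),
                    assay$dye_sdlog)
      cd34 <- rlnorm(n_cells,
                     ifelse(cls == "blast", assay$marker_meanlog[["positive"]],
                            assay$marker_meanlog[["negative"]]),
                     assay$marker_sdlog)
      cd3 <- rlnorm(n_cells,
                    ifelse(cls == "T", assay$marker_meanlog[["positive"]],
                           assay$marker_meanlog[["negative"]]),
                    assay$marker_sdlog)

      artifact <- rep(FALSE, n_cells)
      if (assay$artifact_rate > 0) {
        # merged-object segmentation artifacts: implausibly large areas
        artifact <- runif(n_cells) < assay$artifact_rate
        morph[artifact, "area"] <-
          assay$morphology_means["blast", "area"] * runif(sum(artifact), 6, 10)
      }

      df <- data.frame(
        cell_id = sprintf("%s_c%07d", s, seq_len(n_cells)),
        sample_id = s,
        plate_id = layout$plate_id[well_idx],
        well_id = layout$well_id[well_idx],
        treatment = layout$treatment[well_idx],
        concentration_molar = layout$concentration_molar[well_idx],
        replicate = layout$replicate[well_idx],
        stringsAsFactors = FALSE
      )
      df <- cbind(df, as.data.frame(morph))
      df$dye_intensity <- dye
      df$CD34 <- cd34
      df$CD3 <- cd3
      df$latent_class <- cls
      df$latent_viable <- viab
      df$latent_artifact <- artifact
      df
    })
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
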