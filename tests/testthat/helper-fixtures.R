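# Shared fixture builders (everything generated in code at test time).

# tiny cohort + layout for fast end-to-end runs
tiny_cohort <- function(seed = 1, n_samples = 4, n_compounds = 6) {
  lib <- default_compound_library()
  sel <- lib[round(seq(1, nrow(lib), length.out = n_compounds)), ]
  layout <- generate_plate_layout(n_compounds = n_compounds, n_plates = 1,
                                  n_controls_per_plate = 16, seed = seed,
                                  compounds = sel$compound)
  truth <- simulate_cohort_truth(
    cohort_config(n_samples = n_samples, compounds = sel, mrd_nd_n = 0),
    seed = seed)
  list(layout = layout, truth = truth, compounds = sel)
}

# hand-built well summaries: one row per well from explicit counts
make_summary <- function(treatment, concentration, replicate, n_total,
                         n_viable, n_viable_blast, sample_id = "S1") {
  n_other <- n_viable - n_viable_blast
  df <- data.frame(
    sample_id = sample_id, plate_id = "P1",
    well_id = sprintf("W%02d", seq_along(treatment)),
    treatment = treatment, concentration_molar = concentration,
    replicate = replicate, n_total = n_total, n_viable = n_viable,
    n_viable_blast = n_viable_blast, n_viable_T = 0L,
    n_viable_other = n_other, stringsAsFactors = FALSE
  )
  df$viable_blast_fraction <- ifelse(df$n_viable > 0,
                                     df$n_viable_blast / df$n_viable, NA_real_)
  df$flagged <- df$n_viable == 0
  class(df) <- c("well_summary", "data.frame")
  df
}

# dose series straight from vectors
make_series <- function(concentration, value, replicate = NULL) {
  if (is.null(replicate)) {
    replicate <- stats::ave(seq_along(concentration), concentration,
                            FUN = seq_along)
  }
  structure(data.frame(concentration = concentration, replicate = replicate,
                       value = value),
            sample_id = "S1", compound = "cmp",
            value_kind = "relative-blast-fraction",
            class = c("dose_series", "data.frame"))
}

# cell table with explicit per-well channel means (constant within well)
make_qc_table <- function(well_values, channel = "dye_intensity",
                          cells_per_well = 3) {
  n <- length(well_values)
  df <- data.frame(
    cell_id = sprintf("c%04d", seq_len(n * cells_per_well)),
    plate_id = "P1",
    well_id = rep(sprintf("W%02d", seq_len(n)), each = cells_per_well),
    stringsAsFactors = FALSE
  )
  df[[channel]] <- rep(well_values, each = cells_per_well)
  df
}

# bimodal viability table for labeling tests: two morphology clusters,
# dye modes separated by `sep_sd` component SDs on the log scale
make_viability_table <- function(n = 4000, sep_sd = 10, seed = 1,
                                 viable_frac = 0.7) {
  withr::with_seed(seed, {
    cl <- sample(c("blast", "other"), n, replace = TRUE)
    viable <- stats::runif(n) < viable_frac
    mu <- ifelse(cl == "blast", 3, -3)
    morph <- cbind(
      area = stats::rnorm(n, mu, 1), perimeter = stats::rnorm(n, mu, 1),
      eccentricity = stats::rnorm(n, 0, 1),
      intensity_mean = stats::rnorm(n, mu / 2, 1),
      texture_contrast = stats::rnorm(n, 0, 1),
      texture_entropy = stats::rnorm(n, 0, 1)
    )
    sdlog <- 3 / sep_sd
    dye <- stats::rlnorm(n, ifelse(viable, log(100), log(100) + 3 * log(10)),
                         sdlog * log(10))
    out <- data.frame(cell_id = sprintf("c%06d", seq_len(n)),
                      well_id = "W01", stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(morph))
    out$dye_intensity <- dye
    out$latent_class <- cl
    out$latent_viable <- viable
    out
  })
}
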