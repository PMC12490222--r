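#' Configuration for the synthetic accessibility region matrices
#'
#' Declares a consensus region set, per-cell-type signature regions with a
#' log2 accessibility effect, a negative-binomial count noise model, and
#' the number of labeled healthy reference samples per cell type. Cohort
#' sample profiles are mixtures of the cell-type mean profiles weighted by
#' each sample's latent state probabilities.
#'
#' @param n_regions Number of consensus regions (default 2000).
#' @param n_signature Signature regions per cell type (default 80).
#' @param signature_log2fc Accessibility log2 fold-change of a signature
#'   region in its own cell type (default 2; 0 removes all signal).
#' @param nb_size Negative-binomial size (dispersion) parameter.
#' @param n_ref_per_type Healthy reference samples per cell type.
#' @param base_meanlog,base_sdlog Lognormal prior for region baseline
#'   mean counts.
#' @param libsize_sdlog Per-sample lognormal library-size factor SD.
#' @return A list of class `region_config`.
#' @export
region_config <- function(n_regions = 2000, n_signature = 80,
                          signature_log2fc = 2, nb_size = 20,
                          n_ref_per_type = 6, base_meanlog = log(100),
                          base_sdlog = 0.8, libsize_sdlog = 0.15) {
  stopifnot(n_regions >= 1, n_signature >= 0, nb_size > 0)
  structure(list(
    n_regions = n_regions, n_signature = n_signature,
    signature_log2fc = signature_log2fc, nb_size = nb_size,
    n_ref_per_type = n_ref_per_type, base_meanlog = base_meanlog,
    base_sdlog = base_sdlog, libsize_sdlog = libsize_sdlog
  ), class = "region_config")
}

#' Simulate a labeled healthy reference and cohort region-count matrices
#'
#' Builds a regions x samples count matrix for a labeled healthy
#' hematopoietic reference (each cell type elevates its own signature
#' regions by `signature_log2fc`) and for the cohort, whose per-sample
#' mean profiles are state-probability-weighted mixtures of the cell-type
#' profiles. Counts are negative binomial; region coordinates are emitted
#' as a BED-style table.
#'
#' @param truth A [simulate_cohort_truth()] result (supplies cell types
#'   and per-sample state probabilities).
#' @param config A [region_config()].
#' @param seed Integer seed.
#' @return A list of class `region_matrices` with elements `reference`
#'   (regions x reference samples), `reference_labels`, `cohort`
#'   (regions x cohort samples), `regions` (data.frame `region_id`,
#'   `chrom`, `start`, `end`) and `signatures` (list of signature region
#'   ids per cell type).
#' @export
simulate_region_matrix <- function(truth, config = region_config(), seed = 1) {
  stopifnot(inherits(truth, "cohort_truth"))
  types <- truth$config$cell_types
  if (length(types) < 2) stop("at least 2 cell types are required")
  if (config$n_ref_per_type < 2) {
    stop("at least 2 reference samples per cell type are required")
  }
  if (config$n_signature * length(types) > config$n_regions) {
    stop("n_regions too small for disjoint per-type signature sets")
  }
  with_seed(stream_seed(seed, "regions"), {
    nr <- config$n_regions
    region_id <- sprintf("region_%05d", seq_len(nr))
    regions <- data.frame(
      region_id = region_id, chrom = "chr1",
      start = (seq_len(nr) - 1L) * 1000L + 1L,
      end = (seq_len(nr) - 1L) * 1000L + 500L,
      stringsAsFactors = FALSE
    )
    base <- rlnorm(nr, config$base_meanlog, config$base_sdlog)
    sig_idx <- split(
      sample.int(nr, config$n_signature * length(types)),
      rep(types, each = config$n_signature)
    )[types]
    # per-type mean profile
    type_mu <- vapply(types, function(t) {
      mu <- base
      mu[sig_idx[[t]]] <- mu[sig_idx[[t]]] * 2^config$signature_log2fc
      mu
    }, numeric(nr))

    n_ref <- config$n_ref_per_type * length(types)
    ref_labels <- rep(types, each = config$n_ref_per_type)
    ref_lib <- exp(rnorm(n_ref, 0, config$libsize_sdlog))
    reference <- vapply(seq_len(n_ref), function(j) {
      rnbinom(nr, mu = type_mu[, ref_labels[j]] * ref_lib[j],
              size = config$nb_size)
    }, numeric(nr))
    dimnames(reference) <- list(region_id,
                                sprintf("ref_%s_%02d", ref_labels,
                                        sequence(rep(config$n_ref_per_type,
                                                     length(types)))))

    cohort_ids <- truth$samples$sample_id
    coh_lib <- exp(rnorm(length(cohort_ids), 0, config$libsize_sdlog))
    cohort <- vapply(seq_along(cohort_ids), function(j) {
      mu <- as.numeric(type_mu %*% truth$states[cohort_ids[j], types])
      rnbinom(nr, mu = mu * coh_lib[j], size = config$nb_size)
    }, numeric(nr))
    dimnames(cohort) <- list(region_id, cohort_ids)

    structure(list(
      reference = reference,
      reference_labels = setNames(ref_labels, colnames(reference)),
      cohort = cohort, regions = regions,
      signatures = lapply(sig_idx, function(i) region_id[i]),
      config = config
    ), class = "region_matrices")
  })
}
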