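#' Configuration for the synthetic cohort generator
#'
#' Declares the cohort size, the Dirichlet prior over healthy cell-state
#' probabilities, and the planted effect sizes that couple cell states to
#' compound potencies and drug response to clinical outcome. The defaults
#' are the study conditions the downstream analyses assume: 45 samples,
#' the 115-compound library of [default_compound_library()], a
#' granulocyte-macrophage-progenitor-dominated state prior with a subset
#' of samples pushed toward the monocytic or HSC differentiation extreme,
#' a shared apoptotic-priming factor that couples HDAC/proteasome
#' inhibitors and venetoclax combinations positively and FLT3 inhibitors
#' negatively, an HSC-probability effect on venetoclax-class maximal kill,
#' and measurable-residual-disease (MRD) probabilities that are a logistic
#' function of mean chemotherapy kill plus a differentiation-extreme term.
#'
#' Setting every entry of `effects` to zero yields statistically
#' independent state and potency draws.
#'
#' @param n_samples Number of cohort samples.
#' @param compounds Compound annotation data.frame (`compound`, `class`).
#' @param cell_types Healthy reference cell types.
#' @param alpha_base Dirichlet concentration per cell type (recycled /
#'   matched by name).
#' @param p_extreme Probability that a sample sits at a differentiation
#'   extreme (split evenly between monocyte-like and HSC-like).
#' @param extreme_boost Added Dirichlet concentration on the extreme type.
#' @param effects Named list of planted effect sizes; see Details.
#' @param potency_sd Per-sample/compound logit-normal potency jitter.
#' @param ec50_sdlog Per-sample lognormal EC50 jitter (log10 scale uses
#'   natural-log sd here).
#' @param mrd_nd_n Number of samples whose MRD1 status is not determined.
#' @details `effects` entries: `hsc_venetoclax` (HSC probability raises
#'   venetoclax-class maximal kill on the logit scale), `priming`
#'   (shared latent factor loading for HDAC/proteasome/BCL2/venetoclax
#'   combination classes), `flt3` (loading of the same factor for FLT3
#'   inhibitors; negative plants the opposing axis), `chemo` (latent
#'   chemosensitivity factor loading for chemotherapy), `mrd_chemo`
#'   (logistic coefficient of standardized mean chemotherapy kill on MRD
#'   burden; negative means sensitive samples clear disease), `mrd_extreme`
#'   (MRD-burden shift for samples at a differentiation extreme),
#'   `mrd_noise_sd`, `risk_noise_sd` and `relapse_scale`.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 45,
                          compounds = default_compound_library(),
                          cell_types = c("HSC", "MPP", "lpMPP", "CMP", "GMP",
                                         "MEP", "monocyte", "erythroblast"),
                          alpha_base = c(HSC = 0.9, MPP = 0.9, lpMPP = 0.5,
                                         CMP = 1.3, GMP = 2.6, MEP = 1.2,
                                         monocyte = 1.4, erythroblast = 0.5),
                          p_extreme = 0.4,
                          extreme_boost = 8,
                          effects = list(),
                          potency_sd = 0.8,
                          ec50_sdlog = 0.25,
                          mrd_nd_n = 13) {
  eff <- list(
    hsc_venetoclax = 3, priming = 1.3, flt3 = -1.6, chemo = 1.4,
    chemo_extreme = 1.5, mrd_chemo = -2.2, mrd_extreme = 2.0,
    mrd_noise_sd = 0.5, risk_noise_sd = 0.7, relapse_scale = 1
  )
  eff[names(effects)] <- effects
  if (any(alpha_base <= 0)) stop("Dirichlet concentrations must be positive")
  if (p_extreme < 0 || p_extreme > 1) stop("p_extreme must lie in [0, 1]")
  if (potency_sd < 0 || ec50_sdlog < 0) stop("noise SDs must be nonnegative")
  stopifnot(all(c("compound", "class") %in% names(compounds)))
  if (!all(names(alpha_base) %in% cell_types)) {
    alpha_base <- setNames(rep_len(alpha_base, length(cell_types)), cell_types)
  }
  structure(list(
    n_samples = n_samples, compounds = compounds, cell_types = cell_types,
    alpha_base = alpha_base[cell_types], p_extreme = p_extreme,
    extreme_boost = extreme_boost, effects = eff, potency_sd = potency_sd,
    ec50_sdlog = ec50_sdlog, mrd_nd_n = mrd_nd_n
  ), class = "cohort_config")
}

# Class-level baseline potency priors: mean maximal kill (Beta parameters)
# and off-target kill priors. Chemotherapy is broadly active with high
# off-target kill; targeted agents are active in subsets with low
# off-target activity.
.class_priors <- function(class) {
  switch(class,
    "chemotherapy" = list(kill = c(5, 3), off = c(5, 3)),
    "BCL2 inhibitor" = list(kill = c(4, 4), off = c(2, 8)),
    "venetoclax combination" = list(kill = c(5, 3), off = c(2.5, 7)),
    "HDAC inhibitor" = list(kill = c(4, 4), off = c(2, 8)),
    "proteasome inhibitor" = list(kill = c(4, 3.5), off = c(2, 8)),
    "FLT3 inhibitor" = list(kill = c(3.5, 4.5), off = c(1.5, 9)),
    "kinase inhibitor" = list(kill = c(2.5, 6), off = c(1.5, 9)),
    list(kill = c(2, 6), off = c(1.5, 9))
  )
}

#' Simulate ground-truth cohort records
#'
#' Draws per-sample healthy cell-state probability vectors, per-compound
#' Hill-curve potencies (maximal kill, EC50, slope) whose distribution
#' depends on latent cell states and shared response factors, per-compound
#' off-target kill fractions, and clinical labels (MRD status with percent
#' burden, AIEOP-BFM-style risk group, relapse and follow-up times) coupled
#' to the planted response effects. The full effect configuration is
#' recorded in the returned object so recovery tests know the truth.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; the same seed reproduces the truth bitwise.
#' @return A list of class `cohort_truth` with elements `samples`
#'   (data.frame of latent factors and clinical labels), `states`
#'   (samples x cell-type probability matrix), `maxkill`, `ec50`, `slope`
#'   (samples x compounds matrices), `offtarget` (per-compound kill
#'   fraction on non-blast cells), `expected_midkill` (expected blast kill
#'   at the middle screening concentration), `concentrations`
#'   (compounds x 3 molar grid), `compounds` and `config`.
#' @export
simulate_cohort_truth <- function(config = cohort_config(), seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  eff <- config$effects
  cmp <- config$compounds
  n <- config$n_samples
  nc <- nrow(cmp)
  types <- config$cell_types

  with_seed(seed, {
    ## per-compound baselines
    base_kill <- numeric(nc)
    offtarget <- numeric(nc)
    for (j in seq_len(nc)) {
      pr <- .class_priors(cmp$class[j])
      base_kill[j] <- rbeta(1, pr$kill[1], pr$kill[2])
      offtarget[j] <- rbeta(1, pr$off[1], pr$off[2])
    }
    conc_grid <- matrix(rep(c(1e-7, 1e-6, 1e-5), each = nc), nrow = nc,
                        dimnames = list(cmp$compound, NULL))
    base_ec50 <- 10^runif(nc, -7.2, -5.8)
    base_slope <- exp(rnorm(nc, 0, 0.2))

    ## per-sample latent structure
    extreme <- sample(c("none", "monocyte", "HSC"), n, replace = TRUE,
                      prob = c(1 - config$p_extreme, config$p_extreme / 2,
                               config$p_extreme / 2))
    states <- do.call(rbind, lapply(seq_len(n), function(i) {
      alpha <- config$alpha_base
      if (extreme[i] %in% names(alpha)) {
        alpha[extreme[i]] <- alpha[extreme[i]] + config$extreme_boost
      }
      rdirichlet1(alpha)
    }))
    colnames(states) <- types
    sample_id <- sprintf("S%02d", seq_len(n))
    rownames(states) <- sample_id

    priming <- rnorm(n)
    # differentiation extremes are chemotherapy-resistant primitive /
    # monocytic states: they depress the latent chemosensitivity factor
    chemo_factor <- rnorm(n) -
      eff$chemo_extreme * as.numeric(extreme != "none")

    ven_classes <- c("BCL2 inhibitor", "venetoclax combination")
    priming_classes <- c("HDAC inhibitor", "proteasome inhibitor", ven_classes)

    logit_kill <- matrix(rep(qlogis(pmin(pmax(base_kill, 1e-4), 1 - 1e-4)),
                             each = n), nrow = n)
    for (j in seq_len(nc)) {
      cl <- cmp$class[j]
      if (cl %in% ven_classes) {
        logit_kill[, j] <- logit_kill[, j] +
          eff$hsc_venetoclax * (states[, "HSC"] - mean(states[, "HSC"]))
      }
      if (cl %in% priming_classes) {
        logit_kill[, j] <- logit_kill[, j] + eff$priming * priming
      }
      if (cl == "FLT3 inhibitor") {
        logit_kill[, j] <- logit_kill[, j] + eff$flt3 * priming
      }
      if (cl == "chemotherapy") {
        logit_kill[, j] <- logit_kill[, j] + eff$chemo * chemo_factor
      }
    }
    logit_kill <- logit_kill + matrix(rnorm(n * nc, 0, config$potency_sd),
                                      nrow = n)
    maxkill <- plogis(logit_kill)
    ec50 <- matrix(rep(base_ec50, each = n), nrow = n) *
      exp(matrix(rnorm(n * nc, 0, config$ec50_sdlog), nrow = n))
    slope <- matrix(rep(base_slope, each = n), nrow = n)
    dimnames(maxkill) <- dimnames(ec50) <- dimnames(slope) <-
      list(sample_id, cmp$compound)

    mid <- matrix(rep(conc_grid[, 2], each = n), nrow = n)
    expected_midkill <- maxkill * hill_effect(mid, ec50, slope)
    dimnames(expected_midkill) <- list(sample_id, cmp$compound)

    ## clinical coupling
    chemo_cols <- cmp$class == "chemotherapy"
    if (!any(chemo_cols)) chemo_cols <- rep(TRUE, nc)
    mean_chemo_kill <- rowMeans(expected_midkill[, chemo_cols, drop = FALSE])
    s_chemo <- sd(mean_chemo_kill)
    z_chemo <- if (!is.na(s_chemo) && s_chemo > 0) {
      (mean_chemo_kill - mean(mean_chemo_kill)) / s_chemo
    } else {
      rep(0, n)
    }
    ext_ind <- as.numeric(extreme != "none")
    # log10 MRD burden (% blasts); status threshold 0.1 %, endpoint 1 %
    mrd_burden <- -1.2 + eff$mrd_chemo * z_chemo + eff$mrd_extreme * ext_ind +
      rnorm(n, 0, eff$mrd_noise_sd)
    mrd1_percent <- round(10^mrd_burden, 4)
    mrd1 <- ifelse(mrd1_percent >= 0.1, "pos", "neg")
    nd <- sample.int(n, min(config$mrd_nd_n, n))
    mrd1[nd] <- "not-determined"
    mrd1_percent[nd] <- NA_real_
    mrd2_burden <- mrd_burden - 1.2 + rnorm(n, 0, 0.4)
    mrd2 <- ifelse(10^mrd2_burden >= 0.1, "pos", "neg")
    mrd2[nd] <- "not-determined"

    risk_score <- -z_chemo + 0.9 * ext_ind + rnorm(n, 0, eff$risk_noise_sd)
    qs <- quantile(risk_score, c(0.25, 0.70))
    breaks <- c(-Inf, qs, Inf)
    risk <- if (anyDuplicated(breaks)) {
      factor(rep("IR", n), c("SR", "IR", "HR"))  # degenerate tiny cohorts
    } else {
      cut(risk_score, breaks, labels = c("SR", "IR", "HR"))
    }

    followup_day <- round(runif(n, 150, 2500))
    relapse_p <- plogis(-1.1 + eff$relapse_scale * risk_score)
    relapsed <- rbinom(n, 1, relapse_p) == 1
    relapse_day <- ifelse(relapsed, round(rexp(n, 1 / 380)) + 30, NA_real_)
    relapse_day <- pmin(relapse_day, followup_day)

    samples <- data.frame(
      sample_id = sample_id, extreme = extreme, priming = priming,
      chemo_factor = chemo_factor, mean_chemo_kill = mean_chemo_kill,
      mrd1 = mrd1, mrd1_percent = mrd1_percent, mrd2 = mrd2,
      risk = as.character(risk), relapse_day = as.integer(relapse_day),
      followup_day = as.integer(followup_day), stringsAsFactors = FALSE
    )

    structure(list(
      samples = samples, states = states, maxkill = maxkill, ec50 = ec50,
      slope = slope, offtarget = setNames(offtarget, cmp$compound),
      expected_midkill = expected_midkill, concentrations = conc_grid,
      compounds = cmp, config = config, seed = as.integer(seed)
    ), class = "cohort_truth")
  })
}

#' @export
print.cohort_truth <- function(x, ...) {
  cat(sprintf(
    "<cohort_truth> %d samples x %d compounds; extremes: %s\n",
    nrow(x$samples), nrow(x$compounds),
    paste(names(table(x$samples$extreme)), table(x$samples$extreme),
          sep = "=", collapse = ", ")
  ))
  invisible(x)
}

#' Extract the clinical-label table from a cohort truth object
#'
#' @param truth A `cohort_truth` object.
#' @return A data.frame with columns `sample_id`, `mrd1`, `mrd1_percent`,
#'   `mrd2`, `risk`, `relapse_day`, `followup_day`.
#' @export
clinical_labels <- function(truth) {
  stopifnot(inherits(truth, "cohort_truth"))
  truth$samples[, c("sample_id", "mrd1", "mrd1_percent", "mrd2", "risk",
                    "relapse_day", "followup_day")]
}
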