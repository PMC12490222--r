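#' Parameters for semi-supervised viability labeling
#'
#' @param n_components Dimensionality of the morphology reduction.
#' @param reduce Reduction method: `"pca"` (default) or `"umap"`
#'   (requires the uwot package; slower).
#' @param max_clusters Largest number of morphology clusters considered by
#'   the model-based clustering stage.
#' @param min_cluster_size Clusters smaller than this are treated as
#'   density noise and left unlabeled; it is also the minimum size for
#'   fitting the per-cluster dye mixture.
#' @param cluster_subsample Number of cells the clustering model is fit
#'   on (all cells are then classified).
#' @param sd_away Confidence cut: a cell must lie at least this many
#'   component SDs away from the opposite dye component to be labeled.
#'   Raising this cut can only remove labels.
#' @param sd_within A labeled cell must additionally lie within this many
#'   SDs of its own component (default 3; `Inf` disables the
#'   within-component condition and recovers the pure "away" reading).
#' @param knn_k Neighbour count of the KNN consensus filter.
#' @param knn_ref_size Size of the seeded reference subsample the KNN
#'   votes are computed against.
#' @param polarity `"high-dead"` (default: the higher-intensity dye
#'   component marks membrane-compromised, nonviable cells) or
#'   `"high-viable"` to flip the convention.
#' @param dye_transform Transform applied to dye intensities before the
#'   mixture fit (default `log10`; intensities are lognormal).
#' @param morphology_cols Morphology feature columns.
#' @param seed Integer seed for the subsampling stages.
#' @return A list of class `viability_params`.
#' @export
viability_params <- function(n_components = 2, reduce = c("pca", "umap"),
                             max_clusters = 6, min_cluster_size = 200,
                             cluster_subsample = 5000, sd_away = 3,
                             sd_within = 3, knn_k = 15, knn_ref_size = 5000,
                             polarity = c("high-dead", "high-viable"),
                             dye_transform = log10,
                             morphology_cols = morphology_features(),
                             seed = 1) {
  structure(list(
    n_components = n_components, reduce = match.arg(reduce),
    max_clusters = max_clusters, min_cluster_size = min_cluster_size,
    cluster_subsample = cluster_subsample, sd_away = sd_away,
    sd_within = sd_within, knn_k = knn_k, knn_ref_size = knn_ref_size,
    polarity = match.arg(polarity), dye_transform = dye_transform,
    morphology_cols = morphology_cols, seed = seed
  ), class = "viability_params")
}

# Two-component univariate Gaussian mixture with unequal variances.
# Candidate fits from mclust's default initialization and from a
# midpoint-split EM start (which rescues strongly unbalanced mixtures the
# hierarchical initialization misses); the highest-likelihood valid fit
# wins. Returns list(mean, sd, pro, classification) or NULL.
.fit_gmm2 <- function(x) {
  if (length(unique(x)) < 3) return(NULL)
  cands <- list()
  as_cand <- function(mean, sigmasq, pro, z, loglik) {
    sdv <- sqrt(sigmasq)
    if (length(sdv) == 1) sdv <- rep(sdv, 2)
    if (length(mean) != 2 || any(!is.finite(c(mean, sdv, loglik))) ||
        any(sdv <= sqrt(.Machine$double.eps))) {
      return(NULL)
    }
    list(mean = as.numeric(mean), sd = as.numeric(sdv),
         pro = as.numeric(pro),
         classification = max.col(z, ties.method = "first"),
         loglik = loglik)
  }
  for (model in c("V", "E")) {
    fit <- tryCatch(
      suppressWarnings(Mclust(x, G = 2, modelNames = model, verbose = FALSE)),
      error = function(e) NULL
    )
    if (!is.null(fit) && fit$G == 2) {
      cands[[length(cands) + 1L]] <-
        as_cand(fit$parameters$mean, fit$parameters$variance$sigmasq,
                fit$parameters$pro, fit$z, fit$loglik)
    }
    cut <- (min(x) + max(x)) / 2
    z0 <- cbind(as.numeric(x <= cut), as.numeric(x > cut))
    if (all(colSums(z0) >= 2)) {
      me_fun <- if (model == "V") mclust::meV else mclust::meE
      fit2 <- tryCatch(
        suppressWarnings(me_fun(data = x, z = z0)),
        error = function(e) NULL
      )
      if (!is.null(fit2) && !is.null(fit2$parameters)) {
        cands[[length(cands) + 1L]] <-
          as_cand(fit2$parameters$mean, fit2$parameters$variance$sigmasq,
                  fit2$parameters$pro, fit2$z, fit2$loglik)
      }
    }
  }
  cands <- Filter(Negate(is.null), cands)
  if (!length(cands)) return(NULL)
  cands[[which.max(vapply(cands, `[[`, numeric(1), "loglik"))]]
}

#' Semi-supervised per-cell viability labeling
#'
#' Implements the five-stage labeling procedure: (1) reduce the morphology
#' features (PCA by default, UMAP optionally); (2) cluster cells in the
#' reduced space with a Gaussian-mixture model fit on a seeded subsample
#' (clusters below `min_cluster_size` are density noise and stay
#' unlabeled); (3) within each cluster, fit a two-component
#' unequal-variance Gaussian mixture to the transformed viability-dye
#' intensities; (4) provisionally label only cells that are at least
#' `sd_away` component SDs away from the opposite component (and within
#' `sd_within` SDs of their own); (5) keep a label only when a
#' k-nearest-neighbour majority vote in the reduced space joined with the
#' scaled dye intensity agrees with the mixture assignment. Under the
#' default polarity the higher-dye-mean component is the nonviable pole.
#'
#' @param cell_table Per-cell table with morphology features and a
#'   `dye_intensity` column.
#' @param params A [viability_params()].
#' @return An object of class `viability_labels`: data.frame fields
#'   `cell_id`, `cluster` (0 = noise), `label`
#'   (`viable`/`nonviable`/`unlabeled`), `z_viable`, `z_nonviable`
#'   (distances in component SD units), plus attributes `labeling_rate`
#'   and `params`.
#' @export
label_viability <- function(cell_table, params = viability_params()) {
  stopifnot(all(params$morphology_cols %in% names(cell_table)),
            "dye_intensity" %in% names(cell_table))
  n <- nrow(cell_table)
  if (n <= params$knn_k) {
    stop("fewer cells than the KNN neighbour count")
  }
  morph <- scale(as.matrix(cell_table[, params$morphology_cols]))
  morph[is.nan(morph)] <- 0
  dye <- params$dye_transform(cell_table$dye_intensity)

  ## stage 1: reduction
  red <- if (params$reduce == "pca") {
    prcomp(morph, rank. = params$n_components)$x
  } else {
    if (!requireNamespace("uwot", quietly = TRUE)) {
      stop("reduce = \"umap\" requires the uwot package")
    }
    with_seed(stream_seed(params$seed, "umap"), {
      uwot::umap(morph, n_components = params$n_components,
                 n_threads = 1, n_sgd_threads = 1)
    })
  }

  ## stage 2: clustering (GMM fit on a subsample, all cells classified)
  cluster <- with_seed(stream_seed(params$seed, "cluster"), {
    idx <- if (n > params$cluster_subsample) {
      sample.int(n, params$cluster_subsample)
    } else {
      seq_len(n)
    }
    fit <- Mclust(red[idx, , drop = FALSE], G = seq_len(params$max_clusters),
                  modelNames = c("EII", "VII", "VVV"), verbose = FALSE)
    if (is.null(fit)) rep(1L, n) else
      as.integer(predict(fit, red)$classification)
  })
  sizes <- table(cluster)
  noise <- as.integer(names(sizes)[sizes < params$min_cluster_size])
  cluster[cluster %in% noise] <- 0L

  ## stage 3: per-cluster two-component dye mixture
  comp_label <- rep(NA_character_, n)   # raw mixture assignment
  conf_pass <- rep(FALSE, n)            # stage-4 confidence filter
  z_viable <- z_nonviable <- rep(NA_real_, n)
  for (cl in setdiff(unique(cluster), 0L)) {
    in_cl <- which(cluster == cl)
    fit <- .fit_gmm2(dye[in_cl])
    if (is.null(fit)) next
    mu <- fit$mean
    sdv <- fit$sd
    dead_comp <- if (params$polarity == "high-dead") which.max(mu) else
      which.min(mu)
    live_comp <- 3L - dead_comp
    zl <- abs(dye[in_cl] - mu[live_comp]) / sdv[live_comp]
    zd <- abs(dye[in_cl] - mu[dead_comp]) / sdv[dead_comp]
    z_viable[in_cl] <- zl
    z_nonviable[in_cl] <- zd
    comp_label[in_cl] <- ifelse(fit$classification == live_comp,
                                "viable", "nonviable")
    ## stage 4: at least sd_away SDs from the opposite component and
    ## within sd_within SDs of the assigned one
    conf_pass[in_cl] <- ifelse(fit$classification == live_comp,
                               zl <= params$sd_within & zd >= params$sd_away,
                               zd <= params$sd_within & zl >= params$sd_away)
  }

  ## stage 5: KNN consensus in reduced space + scaled dye; the KNN model
  ## is trained on the raw mixture assignments, so the confidence cut
  ## only ever removes labels
  label <- rep("unlabeled", n)
  assigned <- which(!is.na(comp_label))
  cand <- which(conf_pass)
  if (length(cand) && length(assigned) > 1) {
    space <- cbind(red, as.numeric(scale(dye)))
    ref <- with_seed(stream_seed(params$seed, "knn"), {
      if (length(assigned) > params$knn_ref_size) {
        sample(assigned, params$knn_ref_size)
      } else {
        assigned
      }
    })
    k <- min(params$knn_k, length(ref))
    vote <- FNN::knn(space[ref, , drop = FALSE],
                     space[cand, , drop = FALSE],
                     cl = factor(comp_label[ref]), k = k)
    agree <- as.character(vote) == comp_label[cand]
    label[cand[agree]] <- comp_label[cand[agree]]
  }

  res <- data.frame(
    cell_id = cell_table$cell_id %||% sprintf("cell%07d", seq_len(n)),
    cluster = cluster, label = label,
    z_viable = z_viable, z_nonviable = z_nonviable,
    stringsAsFactors = FALSE
  )
  attr(res, "labeling_rate") <- mean(label != "unlabeled")
  attr(res, "params") <- params
  class(res) <- c("viability_labels", "data.frame")
  res
}

#' @export
print.viability_labels <- function(x, ...) {
  tab <- table(factor(x$label, c("viable", "nonviable", "unlabeled")))
  cat(sprintf(
    "<viability_labels> %d cells; viable %d, nonviable %d, unlabeled %d (labeling rate %.1f%%)\n",
    nrow(x), tab[["viable"]], tab[["nonviable"]], tab[["unlabeled"]],
    100 * attr(x, "labeling_rate")
  ))
  invisible(x)
}
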