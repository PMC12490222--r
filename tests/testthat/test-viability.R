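test_that("well-separated dye components are labeled accurately", {
  tab <- make_viability_table(n = 6000, sep_sd = 12, seed = 1)
  lab <- label_viability(tab, viability_params(seed = 2,
                                               min_cluster_size = 100))
  labeled <- lab$label != "unlabeled"
  expect_gt(mean(labeled), 0.9)
  acc <- mean((lab$label[labeled] == "viable") == tab$latent_viable[labeled])
  expect_gte(acc, 0.99)
  expect_true(attr(lab, "labeling_rate") <= 1)
  expect_equal(attr(lab, "labeling_rate"), mean(labeled))
})

test_that("cells between the dye components stay unlabeled", {
  tab <- make_viability_table(n = 5000, sep_sd = 12, seed = 3)
  # inject cells exactly at the midpoint of the two log-intensity modes
  mid <- exp((log(100) + log(100) + 3 * log(10)) / 2)
  inj <- tab[1:60, ]
  inj$cell_id <- sprintf("inj%03d", 1:60)
  inj$dye_intensity <- mid
  lab <- label_viability(rbind(tab, inj),
                         viability_params(seed = 2, min_cluster_size = 100))
  inj_lab <- lab$label[lab$cell_id %in% inj$cell_id]
  expect_true(all(inj_lab == "unlabeled"))
  expect_lt(attr(lab, "labeling_rate"), 1)
})

test_that("raising the confidence cut never increases the labeling rate", {
  tab <- make_viability_table(n = 4000, sep_sd = 6, seed = 5)
  r3 <- attr(label_viability(tab, viability_params(seed = 2, sd_away = 3,
                                                   min_cluster_size = 100)),
             "labeling_rate")
  r4 <- attr(label_viability(tab, viability_params(seed = 2, sd_away = 4,
                                                   min_cluster_size = 100)),
             "labeling_rate")
  expect_lte(r4, r3)
})

test_that("flipping the dye polarity convention flips every label", {
  tab <- make_viability_table(n = 3000, sep_sd = 12, seed = 7,
                              viable_frac = 0.5)
  a <- label_viability(tab, viability_params(seed = 2,
                                             min_cluster_size = 100))
  b <- label_viability(tab, viability_params(seed = 2,
                                             min_cluster_size = 100,
                                             polarity = "high-viable"))
  flip <- c(viable = "nonviable", nonviable = "viable",
            unlabeled = "unlabeled")
  expect_identical(unname(flip[a$label]), b$label)
})

test_that("cells in noise clusters are never labeled", {
  tab <- make_viability_table(n = 3000, sep_sd = 12, seed = 9)
  # a well-separated but tiny third morphology cluster
  small <- tab[1:80, ]
  small$cell_id <- sprintf("noise%03d", 1:80)
  for (f in c("area", "perimeter", "intensity_mean")) small[[f]] <- 20
  lab <- label_viability(rbind(tab, small),
                         viability_params(seed = 2, min_cluster_size = 200,
                                          max_clusters = 6))
  noise_cells <- lab$cell_id %in% small$cell_id
  if (any(lab$cluster[noise_cells] == 0)) {
    expect_true(all(lab$label[noise_cells][lab$cluster[noise_cells] == 0] ==
                      "unlabeled"))
  }
  expect_true(all(lab$label[lab$cluster == 0] == "unlabeled"))
})

test_that("a mislabeled island is vetoed by the KNN consensus", {
  withr::with_seed(11, {
    n <- 1545
    morph <- matrix(rnorm(n * 6, 0, 1), ncol = 6,
                    dimnames = list(NULL, c("area", "perimeter",
                                            "eccentricity", "intensity_mean",
                                            "texture_contrast",
                                            "texture_entropy")))
    # 1500 viable cells in the main morphology cluster, a 40-cell
    # nonviable morphology cluster far away (too small: density noise),
    # and a 5-cell nonviable-dye island embedded in the viable cluster
    viable <- rep(c(TRUE, FALSE), c(1505, 40))
    dye <- rlnorm(n, ifelse(viable, log(100), log(100) + 3 * log(10)), 0.25)
    morph[!viable, ] <- morph[!viable, ] + 8
    island <- 1:5
    dye[island] <- exp(log(100) + 3 * log(10))
    tab <- data.frame(cell_id = sprintf("c%05d", 1:n), well_id = "W01",
                      morph, dye_intensity = dye,
                      stringsAsFactors = FALSE)
  })
  lab <- label_viability(tab, viability_params(seed = 2, knn_k = 25,
                                               min_cluster_size = 100))
  # the island's mixture assignment is nonviable, but its neighbourhood in
  # the consensus space is viable-labeled: the labels are withheld
  expect_true(all(lab$label[1:5] == "unlabeled"))
  # the bulk of ordinary cells is still labeled
  expect_gt(attr(lab, "labeling_rate"), 0.5)
})

test_that("labeling refuses tables smaller than the neighbour count", {
  tab <- make_viability_table(n = 10, seed = 1)
  expect_error(label_viability(tab, viability_params(knn_k = 15)),
               "fewer cells")
})
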