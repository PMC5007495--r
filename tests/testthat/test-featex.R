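make_peaks <- function(rc, cell = 0L, intensity = 1000) {
  data.frame(peak_id = seq_len(nrow(rc)) - 1L, row = rc[, 1], col = rc[, 2],
             intensity_counts = intensity, cell_id = cell, excluded = FALSE)
}

test_that("cell features reproduce the 3-4-5 geometry by hand", {
  ct <- disc_contour(c(32, 32), 20, 64, 64)
  pk <- make_peaks(cbind(c(25, 28, 31), c(25, 29, 33)))   # 0,0 / 3,4 / 6,8
  cf <- cell_features(ct, pk, 0.16)
  expect_equal(cf$n_peaks, 3)
  expect_equal(cf$mean_pairwise_distance_um, (5 + 5 + 10) / 3 * 0.16)
  expect_equal(cf$mean_nearest_distance_um, 5 * 0.16)
  expect_equal(cf$area_um2, ct$area_px * 0.16^2)
  # single peak: distances undefined
  cf1 <- cell_features(ct, pk[1, ], 0.16)
  expect_true(is.na(cf1$mean_pairwise_distance_um))
  expect_true(is.na(cf1$mean_nearest_distance_um))
  expect_equal(cf1$mean_peak_intensity, 1000)
  # zero peaks: intensity undefined too
  cf0 <- cell_features(ct, pk[0, ], 0.16)
  expect_equal(cf0$n_peaks, 0)
  expect_true(is.na(cf0$mean_peak_intensity))
  # edge cells must have been filtered upstream
  edge <- ct; edge$touches_edge <- TRUE
  expect_error(cell_features(edge, pk, 0.16), "edge-flagged")
})

test_that("distance features equal the O(n^2) brute-force oracle", {
  ct <- disc_contour(c(40, 40), 30, 80, 80)
  set.seed(5)
  for (rep in 1:5) {
    n <- sample(3:10, 1)
    rc <- cbind(sample(20:60, n), sample(20:60, n))
    cf <- cell_features(ct, make_peaks(rc), 0.16)
    pw <- nn <- c()
    for (i in 1:n) {
      di <- c()
      for (j in 1:n) {
        if (i == j) next
        d <- sqrt(sum((rc[i, ] - rc[j, ])^2))
        if (j > i) pw <- c(pw, d)
        di <- c(di, d)
      }
      nn <- c(nn, min(di))
    }
    expect_equal(cf$mean_pairwise_distance_um, mean(pw) * 0.16)
    expect_equal(cf$mean_nearest_distance_um, mean(nn) * 0.16)
  }
})

test_that("image features match a hand-computed two-cell scene", {
  H <- W <- 96
  c1 <- disc_contour(c(30, 30), 12, H, W, 0L)
  c2 <- disc_contour(c(70, 70), 12, H, W, 1L)
  cts <- flag_edge_cells(list(c1, c2), c(H, W))
  # cell 0: two peaks (3-4-5 pair); cell 1: one peak
  pk <- rbind(make_peaks(cbind(c(27, 30), c(26, 30)), 0L, c(2000, 4000)),
              make_peaks(cbind(70, 70), 1L, 1000))
  frame <- matrix(10, H, W)
  frame[c1$mask] <- 30
  frame[c2$mask] <- 30
  fv <- image_features(cts, pk, frame, 0.16)
  expect_equal(fv$number_of_peaks, 1.5)
  expect_equal(fv$cell_intensity, mean(c(3000, 1000)))
  expect_equal(fv$sd_cell_intensity, sd(c(3000, 1000)))
  expect_equal(fv$peak_density,
               mean(c(2 / (c1$area_px * 0.16^2), 1 / (c2$area_px * 0.16^2))))
  expect_equal(fv$distance_complete, 5 * 0.16)   # only cell 0 has >= 2 peaks
  expect_equal(fv$distance_nearest, 5 * 0.16)
  expect_equal(fv$intensity_ratio, 3)
  expect_equal(fv$n_cells, 2)
  expect_true(fv$has_signal)
  expect_equal(fv$total_peaks, 3)
})

test_that("images without signal stay well-defined", {
  H <- W <- 64
  ct <- flag_edge_cells(list(disc_contour(c(32, 32), 12, H, W)), c(H, W))
  flat <- matrix(50, H, W)
  fv <- image_features(ct, make_peaks(cbind(1, 1))[0, ], flat, 0.16)
  expect_equal(fv$number_of_peaks, 0)
  expect_equal(fv$peak_density, 0)
  expect_equal(fv$cell_intensity, 0)
  expect_equal(fv$distance_complete, 0)
  expect_equal(fv$intensity_ratio, 1)
  expect_false(fv$has_signal)
  # all cells on the edge -> explicit empty-image condition
  edge <- disc_contour(c(2, 32), 6, H, W)
  expect_error(image_features(flag_edge_cells(list(edge), c(H, W)),
                              make_peaks(cbind(1, 1))[0, ], flat, 0.16),
               class = "rhd_empty_image")
})

test_that("features are invariant to cell and peak ordering", {
  sim <- simulate_image("WEAK_D", "H41", n_bf = 1, n_fluo = 1, seed = 88)
  cts <- detect_cells(sim$stack$frames[[1]])
  pk <- assign_peaks(detect_peaks(sim$stack$frames[[2]]), cts)
  fv1 <- image_features(cts, pk, sim$stack$frames[[2]], 0.16)
  set.seed(1)
  fv2 <- image_features(rev(cts), pk[sample.int(nrow(pk)), ],
                        sim$stack$frames[[2]], 0.16)
  expect_equal(fv1, fv2)
})

test_that("intensities scale linearly, geometry does not (scale law)", {
  H <- W <- 96
  cts <- flag_edge_cells(list(disc_contour(c(40, 40), 14, H, W, 0L)), c(H, W))
  pk <- make_peaks(cbind(c(36, 44), c(36, 44)), 0L, c(2000, 3000))
  frame <- matrix(10, H, W); frame[cts[[1]]$mask] <- 25
  f1 <- image_features(cts, pk, frame, 0.16)
  pk2 <- pk; pk2$intensity_counts <- pk$intensity_counts * 3
  f2 <- image_features(cts, pk2, frame * 3, 0.16)
  expect_equal(f2$cell_intensity, 3 * f1$cell_intensity)
  expect_equal(f2$sd_cell_intensity, 3 * f1$sd_cell_intensity)
  expect_equal(f2$intensity_ratio, f1$intensity_ratio)
  expect_equal(f2$number_of_peaks, f1$number_of_peaks)
  expect_equal(f2$distance_complete, f1$distance_complete)
})

test_that("sample features are the column means of the image features", {
  v1 <- data.frame(number_of_peaks = 1, cell_intensity = 10,
                   sd_cell_intensity = 1, peak_density = 0.1,
                   distance_complete = 2, distance_nearest = 1,
                   intensity_ratio = 1.5)
  v3 <- v1 * 3
  sf <- sample_features(rbind(v1, v3))
  expect_equal(sf$number_of_peaks, 2)
  expect_equal(sf$cell_intensity, 20)
  expect_equal(sf$n_images, 2)
  expect_equal(sample_features(v1)[, 1:7], v1)
  set.seed(2)
  many <- as.data.frame(matrix(runif(13 * 7), 13, 7))
  names(many) <- rhdtype:::feature_names()
  sf2 <- sample_features(many)
  for (f in names(many)) expect_equal(sf2[[f]], mean(many[[f]]))
  expect_error(sample_features(many[0, ]), "at least one")
})

test_that("simulated class ordering of cell intensity matches the populations", {
  # H41: D+ > weak D > DEL ~ D- in mean per-peak intensity
  mean_ci <- function(label, n, seed0) {
    vals <- c()
    for (s in seq_len(n)) {
      sim <- simulate_image(label, "H41", n_bf = 1, n_fluo = 1,
                            seed = seed0 + s,
                            intensity = intensity_model(
                              default_intensity_models()$H41[[label]]$mean_peak_intensity,
                              default_intensity_models()$H41[[label]]$sd_peak_intensity,
                              1, 6))
      res <- process_stack(sim$stack)
      if (!is.null(res$features) && res$features$has_signal)
        vals <- c(vals, res$features$cell_intensity)
    }
    mean(vals)
  }
  ci <- vapply(c("D_POS", "WEAK_D", "DEL"), mean_ci, numeric(1), n = 3,
               seed0 = 4000)
  expect_gt(ci[["D_POS"]], ci[["WEAK_D"]])
  expect_gt(ci[["WEAK_D"]], ci[["DEL"]])
})
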