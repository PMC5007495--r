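test_that("a blank noisy frame yields no contours", {
  set.seed(1)
  blank <- matrix(1000 + rnorm(512 * 512, 0, 20), 512, 512)
  expect_length(detect_cells(blank), 0)
  expect_error(detect_cells(array(0, c(4, 4, 2))), "2-D")
})

test_that("interior cells are recovered with IoU >= 0.7 and few false positives", {
  n_frames <- 50
  hits <- misses <- fp <- 0
  ious <- c()
  for (s in seq_len(n_frames)) {
    sim <- simulate_image("D_POS", "H41", n_bf = 1, n_fluo = 1, seed = 200 + s)
    cts <- detect_cells(sim$stack$frames[[1]])
    tc <- sim$truth$cells
    for (k in which(!tc$touches_edge)) {
      ctr <- c(tc$center_row[k], tc$center_col[k])
      best <- 0
      for (ct in cts)
        if (sum((ct$centroid - ctr)^2) <= tc$radius[k]^2)
          best <- max(best, mask_disc_iou(ct, ctr, tc$radius[k]))
      if (best >= 0.7) { hits <- hits + 1; ious <- c(ious, best) }
      else misses <- misses + 1
    }
    for (ct in cts) {
      d <- sqrt((tc$center_row - ct$centroid[1])^2 +
                (tc$center_col - ct$centroid[2])^2)
      if (!any(d <= 1.5 * tc$radius)) fp <- fp + 1
    }
  }
  expect_gte(hits / (hits + misses), 0.95)
  expect_lte(fp / n_frames, 0.05)
  expect_gt(mean(ious), 0.8)
})

test_that("refinement contracts an oversized concentric seed onto the rim", {
  bf <- render_bf_cell(radius = 20, noise_sd = 10, seed = 2)
  seed <- disc_contour(c(64, 64), 1.3 * 20, 128, 128)
  ct <- refine_contour(seed, bf, segmentation_params(cell_radius_mean_px = 20))
  r_hat <- mean(sqrt(rowSums(sweep(ct$nodes, 2, c(64, 64))^2)))
  expect_lt(abs(r_hat - 20) / 20, 0.10)
})

test_that("a seed already on the rim converges immediately", {
  bf <- render_bf_cell(radius = 20, noise_sd = 0)
  # nodes on the gradient ridge (outer rim edge)
  seed <- disc_contour(c(64, 64), 20, 128, 128)
  ct <- refine_contour(seed, bf, segmentation_params(cell_radius_mean_px = 20))
  expect_lte(ct$energy_trace[nrow(ct$energy_trace), "end"],
             ct$energy_trace[1, "start"])
  r_hat <- mean(sqrt(rowSums(sweep(ct$nodes, 2, c(64, 64))^2)))
  expect_lt(abs(r_hat - 20), 1.5)
})

test_that("on a featureless frame the contour shrinks with non-increasing energy", {
  flat <- matrix(500, 128, 128)
  seed <- disc_contour(c(64, 64), 30, 128, 128)
  ct <- refine_contour(seed, flat, segmentation_params())
  expect_lt(ct$area_px, seed$area_px)
  tr <- ct$energy_trace
  expect_true(all(tr[, "end"] <= tr[, "start"] + 1e-9))
  # image energy no worse than the seed's (both zero here)
  expect_lte(ct$image_energy, 1e-12)
})

test_that("degenerate seeds are returned unchanged with a warning", {
  bf <- render_bf_cell()
  tiny <- disc_contour(c(64, 64), 0.4, 128, 128)
  expect_warning(out <- refine_contour(tiny, bf), "degenerate")
  expect_identical(out$nodes, tiny$nodes)
})

test_that("edge flagging is exact, pure and idempotent on ground-truth discs", {
  sim <- simulate_image("WEAK_D", "H41", n_bf = 1, n_fluo = 1, seed = 321)
  tc <- sim$truth$cells
  cts <- lapply(seq_len(nrow(tc)), function(k)
    disc_contour(c(tc$center_row[k], tc$center_col[k]), tc$radius[k],
                 512, 512, tc$cell_id[k]))
  flagged <- flag_edge_cells(cts, c(512, 512))
  got <- vapply(flagged, function(ct) ct$touches_edge, logical(1))
  expect_equal(got, tc$touches_edge)
  # idempotent, and only the flag changes
  again <- flag_edge_cells(flagged, c(512, 512))
  expect_identical(again, flagged)
  expect_identical(lapply(flagged, function(ct) ct[c("nodes", "mask", "area_px")]),
                   lapply(cts, function(ct) ct[c("nodes", "mask", "area_px")]))
})

test_that("single border pixels flip the edge flag", {
  H <- W <- 32
  interior <- disc_contour(c(16, 16), 6, H, W)
  expect_false(flag_edge_cells(list(interior), c(H, W))[[1]]$touches_edge)
  shifted <- disc_contour(c(16, 6), 6.2, H, W)   # mask reaches column 1
  expect_true(any(shifted$mask[, 1]))
  expect_true(flag_edge_cells(list(shifted), c(H, W))[[1]]$touches_edge)
})

test_that("returned contours never overlap by more than 10% of the smaller", {
  for (s in c(207, 219)) {
    sim <- simulate_image("D_POS", "H41", n_bf = 1, n_fluo = 1, seed = s)
    cts <- detect_cells(sim$stack$frames[[1]])
    expect_true(all(vapply(cts, function(ct) ct$area_px >= 3, logical(1))))
    expect_equal(vapply(cts, function(ct) ct$cell_id, integer(1)),
                 seq_along(cts) - 1L)
    if (length(cts) < 2) next
    for (a in seq_along(cts)) for (b in seq_len(a - 1)) {
      ov <- sum(cts[[a]]$mask & cts[[b]]$mask)
      expect_lte(ov, 0.1 * min(cts[[a]]$area_px, cts[[b]]$area_px))
    }
  }
})

test_that("the C++ snake energy agrees with the independent R implementation", {
  set.seed(4)
  G <- matrix(runif(40 * 40), 40, 40)
  nodes <- rhdtype:::circle_nodes(c(20, 20), 8, 16)
  p <- segmentation_params()
  res <- rhdtype:::snake_refine_cpp(G, cbind(nodes[, 1] - 1, nodes[, 2] - 1),
                                    p$snake_alpha, p$snake_beta, p$snake_gamma,
                                    1L, 1e-9, 0.5, p$snake_pressure)
  e_r <- rhdtype:::snake_energy(nodes, G, p$snake_alpha, p$snake_beta,
                                p$snake_gamma, p$snake_pressure)
  expect_equal(res$energy_start[1], e_r, tolerance = 1e-8)
})

test_that("the (1+1)-ES polish only ever improves the snake energy", {
  bf <- render_bf_cell(radius = 20, noise_sd = 5, seed = 9)
  p0 <- segmentation_params(cell_radius_mean_px = 20)
  p1 <- segmentation_params(cell_radius_mean_px = 20, es_polish = TRUE,
                            es_iterations = 40)
  seed <- disc_contour(c(64, 64), 26, 128, 128)
  G <- rhdtype:::gradient_field(bf, p0)
  set.seed(11)
  plain <- refine_contour(seed, bf, p0, gradient = G)
  set.seed(11)
  polished <- refine_contour(seed, bf, p1, gradient = G)
  e <- function(ct) rhdtype:::snake_energy(ct$nodes, G, p0$snake_alpha,
                                           p0$snake_beta, p0$snake_gamma)
  expect_lte(e(polished), e(plain) + 1e-9)
})
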