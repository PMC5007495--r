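test_that("default manifest mirrors the published cohort", {
  m <- build_default_manifest(seed = 0)
  expect_equal(nrow(m), 51)
  expect_equal(sum(m$label == "D_POS"), 12)
  expect_equal(sum(m$label == "WEAK_D"), 14)
  expect_equal(sum(m$label == "DEL"), 12)
  expect_equal(sum(m$label == "D_NEG"), 13)
  expect_false(anyDuplicated(m$sample_id) > 0)
  expect_true(all(m$images_per_sample >= 11 & m$images_per_sample <= 15))
  expect_true(all(m$seed >= 1 & m$seed < 2^31))
  # both branches of the image-count rule reachable in a default cohort
  expect_true(any(m$images_per_sample >= 11))
  # deterministic in the seed
  expect_identical(m, build_default_manifest(seed = 0))
  expect_false(identical(m$seed, build_default_manifest(seed = 1)$seed))
})

test_that("manifest respects a custom image range and round-trips as CSV", {
  m <- build_default_manifest(seed = 3, images_range = c(5L, 5L))
  expect_true(all(m$images_per_sample == 5))
  path <- tempfile(fileext = ".csv")
  write_manifest(m, path)
  expect_equal(read_manifest(path), m)
  expect_error(suppressWarnings(read_manifest(tempfile())), "cannot open")
})

test_that("simulated stacks are bitwise deterministic in the seed", {
  g <- small_geometry()
  a <- simulate_image("WEAK_D", "H41", g, n_bf = 1, n_fluo = 1, seed = 42)
  b <- simulate_image("WEAK_D", "H41", g, n_bf = 1, n_fluo = 1, seed = 42)
  expect_identical(a$stack$frames, b$stack$frames)
  expect_identical(a$truth, b$truth)
  c <- simulate_image("WEAK_D", "H41", g, n_bf = 1, n_fluo = 1, seed = 43)
  expect_false(identical(a$stack$frames, c$stack$frames))

  entry <- list(sample_id = "S01", label = "DEL", channel = "H41",
                images_per_sample = 2L, seed = 77L)
  s1 <- simulate_sample(entry, g, n_bf = 1, n_fluo = 1)
  s2 <- simulate_sample(entry, g, n_bf = 1, n_fluo = 1)
  expect_identical(s1, s2)
  expect_equal(length(s1$images), 2)
})

test_that("stack layout follows the acquisition protocol", {
  sim <- simulate_image("D_NEG", "H41", small_geometry(), n_bf = 3,
                        n_fluo = 2, seed = 5)
  expect_s3_class(sim$stack, "rhd_stack")
  expect_equal(sim$stack$modality, c("BF", "BF", "BF", "FLUO", "FLUO"))
  expect_equal(sim$stack$pixel_pitch_um, 0.16)
  expect_true(all(vapply(sim$stack$frames, function(f)
    all(f >= 0 & f <= 65535 & f == round(f)), logical(1))))
  # default field covers ~82 x 82 um^2
  g <- field_geometry()
  expect_equal(g$width_px, 512L)
  expect_equal(g$width_px * g$pixel_pitch_um, 81.92)
})

test_that("labelled-cell fractions match the population model", {
  g <- small_geometry(rate = 4)
  count_cells <- function(label, n_img, seed0) {
    tot <- lab <- 0
    for (s in seq_len(n_img)) {
      sim <- simulate_image(label, "H41", g, n_bf = 0, n_fluo = 1,
                            seed = seed0 + s)
      tot <- tot + nrow(sim$truth$cells)
      lab <- lab + sum(sim$truth$cells$is_labelled)
    }
    c(tot, lab)
  }
  del <- count_cells("DEL", 70, 1000)       # >= 200 cells
  expect_gt(del[1], 200)
  expect_lt(abs(del[2] / del[1] - 0.10), 0.05)
  dneg <- count_cells("D_NEG", 300, 2000)   # ~1000 cells
  expect_gt(dneg[1], 800)
  expect_lt(abs(dneg[2] / dneg[1] - 0.01), 0.01)
})

test_that("every labelled cell carries at least one peak; unlabelled none", {
  g <- small_geometry()
  for (s in 1:6) {
    sim <- simulate_image("D_POS", "H41", g, n_bf = 0, n_fluo = 1,
                          seed = 300 + s)
    tc <- sim$truth$cells
    interior <- tc$cell_id[!tc$touches_edge]
    expect_true(all(tc$is_labelled))
    expect_true(all(interior %in% sim$truth$peaks$cell_id))
  }
  zero <- simulate_image("D_POS", "H41", g,
                         intensity = intensity_model(11700, 4000, 0, 30),
                         n_bf = 0, n_fluo = 1, seed = 9)
  expect_equal(nrow(zero$truth$peaks), 0)
})

test_that("true peaks lie inside their cell's disc and away from borders", {
  for (s in 1:4) {
    sim <- simulate_image("D_POS", "H41", small_geometry(), n_bf = 0,
                          n_fluo = 1, seed = 400 + s)
    tc <- sim$truth$cells
    pk <- sim$truth$peaks
    if (nrow(pk) == 0) next
    d <- sqrt((tc$center_row[pk$cell_id + 1] - pk$row)^2 +
              (tc$center_col[pk$cell_id + 1] - pk$col)^2)
    expect_true(all(d <= tc$radius[pk$cell_id + 1] + 0.71))
    expect_true(all(pk$true_3x3_sum >= 0))
    expect_true(all(pk$row >= 2 & pk$row <= 255 & pk$col >= 2 & pk$col <= 255))
  }
})

test_that("drawn 3x3 targets round-trip the population mean (truncation < 2%)", {
  # >= 10^4 peaks pooled over many small D+ fields
  g <- small_geometry(rate = 4)
  sums <- numeric(0)
  s <- 0
  while (length(sums) < 12000) {
    s <- s + 1
    sim <- simulate_image("D_POS", "H41", g, n_bf = 0, n_fluo = 1,
                          seed = 5000 + s)
    sums <- c(sums, sim$truth$peaks$true_3x3_sum)
  }
  expect_lt(abs(mean(sums) - 11700) / 11700, 0.02)
  # analytic oracle: mean of the truncated normal
  nm <- noise_model()
  a <- (9 * nm$background_mean + 3 * nm$background_sd - 11700) / 4000
  mu_trunc <- 11700 + 4000 * dnorm(a) / (1 - pnorm(a))
  expect_lt(abs(mean(sums) - mu_trunc), 3 * 4000 / sqrt(length(sums)))
})

test_that("degenerate inputs fail loudly", {
  expect_error(simulate_image("D_POS", "H41",
                              field_geometry(width_px = 40, height_px = 40)),
               "too small")
  expect_error(intensity_model(100, 10, 0.5, -1), ">= 0")
  expect_error(intensity_model(100, -1, 0.5, 1))
  expect_error(simulate_image("BAD", "H41", small_geometry()), "unknown RhD")
  expect_error(simulate_image("D_POS", "XYZ", small_geometry()),
               "unknown antibody")
})

test_that("photon conversion and noise calibration are fixed", {
  expect_identical(counts_to_photons(1), 0.3)
  expect_equal(counts_to_photons(c(10, 0)), c(3, 0))
  expect_error(noise_model(photons_per_count = 0.5), "fixed at 0.3")
  nm <- noise_model()
  expect_equal(nm$target_snr_mean, 31)
  expect_equal(nm$target_snr_sd, 9)
  # calibration is deterministic and scales inversely with the target
  expect_equal(calibrate_background_sd(target_snr_mean = 31) * 31,
               calibrate_background_sd(target_snr_mean = 62) * 62)
})

test_that("cell count per field matches the configured rate", {
  g <- field_geometry()   # default 8.8 cells / 512^2 field
  n <- vapply(1:60, function(s) {
    sim <- simulate_image("D_NEG", "H41", g, n_bf = 0, n_fluo = 1,
                          seed = 7000 + s)
    nrow(sim$truth$cells)
  }, numeric(1))
  expect_lt(abs(mean(n) - 8.8), 1.2)   # 3 SE + small placement loss
})
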