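# Shared fixtures: everything is generated in code at test time.

# small field for fast simulations
small_geometry <- function(rate = 4) {
  field_geometry(width_px = 256L, height_px = 256L, cells_per_image_rate = rate)
}

# linearly separable toy feature table: classes shifted in every feature
toy_table <- function(n = 50, classes = c("A", "B"), sep = 4, seed = 1) {
  with_seed(seed, {
    lab <- rep(classes, length.out = n)
    X <- matrix(rnorm(n * 7), n, 7)
    for (k in seq_along(classes))
      X[lab == classes[k], ] <- X[lab == classes[k], ] + (k - 1) * sep
    tab <- data.frame(item_id = sprintf("i%03d", seq_len(n)),
                      sample_id = sprintf("i%03d", seq_len(n)),
                      label = lab, X, stringsAsFactors = FALSE)
    names(tab)[4:10] <- rhdtype:::feature_names()
    tab
  })
}

# grouped toy: n_samples samples x images_per images, class-shifted features
toy_grouped_table <- function(n_samples = 15, images_per = 4,
                              classes = c("A", "B"), sep = 5, seed = 2) {
  with_seed(seed, {
    lab_s <- rep(classes, length.out = n_samples)
    n <- n_samples * images_per
    lab <- rep(lab_s, each = images_per)
    X <- matrix(rnorm(n * 7), n, 7)
    for (k in seq_along(classes))
      X[lab == classes[k], ] <- X[lab == classes[k], ] + (k - 1) * sep
    tab <- data.frame(item_id = sprintf("s%02d/%d",
                                        rep(seq_len(n_samples), each = images_per),
                                        rep(seq_len(images_per), n_samples)),
                      sample_id = rep(sprintf("s%02d", seq_len(n_samples)),
                                      each = images_per),
                      label = lab, X, stringsAsFactors = FALSE)
    names(tab)[4:10] <- rhdtype:::feature_names()
    tab
  })
}

# contour whose mask is a disc clipped to the frame (ground-truth shape)
disc_contour <- function(center, radius, H, W, cell_id = 0L) {
  nodes <- rhdtype:::circle_nodes(center, radius, 60)
  nodes[, 1] <- pmin(pmax(nodes[, 1], 1), H)
  nodes[, 2] <- pmin(pmax(nodes[, 2], 1), W)
  rhdtype:::contour_from_nodes(nodes, cell_id, H, W)
}

# render one synthetic bright-field cell directly (no simulator RNG)
render_bf_cell <- function(H = 128, W = 128, center = c(64, 64), radius = 20,
                           noise_sd = 0, seed = 1) {
  with_seed(seed, {
    img <- matrix(1000, H, W)
    d <- sqrt(outer((seq_len(H) - center[1])^2, (seq_len(W) - center[2])^2, "+"))
    img[d <= radius] <- 700
    img[d <= radius - 2] <- 1100
    if (noise_sd > 0) img <- img + matrix(rnorm(H * W, 0, noise_sd), H, W)
    img
  })
}

# IoU of a detected contour mask against a true disc
mask_disc_iou <- function(ct, center, radius) {
  ii <- which(ct$mask, arr.ind = TRUE)
  d <- sqrt((ii[, 1] - center[1])^2 + (ii[, 2] - center[2])^2)
  inter <- sum(d <= radius)
  inter / (ct$area_px + pi * radius^2 - inter)
}
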