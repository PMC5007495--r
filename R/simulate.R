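#' Simulate one bright-field + fluorescence image stack with ground truth
#'
#' Generates a synthetic field of view mimicking the acquisition
#' protocol: `n_bf` bright-field frames of erythrocytes (dark rim,
#' slightly bright interior over background) followed by `n_fluo`
#' fluorescence frames of background plus Gaussian single-molecule peaks.
#' Peak 3x3-sum intensities are drawn directly from the population's
#' normal law (truncated below at `9 * background_mean +
#' 3 * background_sd`) and the PSF amplitude is back-solved from the
#' sub-pixel spot position, so the descriptive statistics of the
#' population round-trip through the detection pipeline by construction.
#'
#' Drawn peak positions are thinned to a minimum mutual separation
#' (`peak_min_sep_px`): the published intensity statistics describe
#' *detected* peaks, and emitters closer than the detection resolution
#' merge into a single peak.
#'
#' @param label RhD phenotype, one of [rhd_labels()].
#' @param channel antibody channel, one of [antibody_channels()].
#' @param geometry [field_geometry()].
#' @param intensity [intensity_model()]; defaults to the
#'   `(label, channel)` entry of [default_intensity_models()].
#' @param noise [noise_model()].
#' @param n_bf,n_fluo frame counts (acquisition order: bright-field
#'   first).
#' @param psf_sigma_px PSF standard deviation, pixels.
#' @param edge_clip_fraction fraction of cells deliberately placed so
#'   the frame border clips them.
#' @param min_sep_factor minimum centre separation between cells, in
#'   units of the mean cell radius (>= 1.5).
#' @param peak_min_sep_px minimum separation between true peaks, pixels.
#' @param bf_levels bright-field rendering levels
#'   `c(background, interior, rim)` in counts.
#' @param bf_noise_sd bright-field pixel noise SD, counts.
#' @param seed optional integer; when given, the current RNG state is
#'   saved and restored and the image is a pure function of the seed.
#' @return list with elements `stack` (class `rhd_stack`: `frames`,
#'   `modality`, `pixel_pitch_um`) and `truth` (list of `cells` and
#'   `peaks` data.frames; coordinates 1-based in memory). Cell ids count
#'   from 0.
#' @export
simulate_image <- function(label, channel = "H41",
                           geometry = field_geometry(),
                           intensity = NULL, noise = noise_model(),
                           n_bf = 10L, n_fluo = 5L, psf_sigma_px = 1,
                           edge_clip_fraction = 0.15, min_sep_factor = 2.3,
                           peak_min_sep_px = 4,
                           bf_levels = c(background = 1000, interior = 1100,
                                         rim = 700),
                           bf_noise_sd = 20, seed = NULL) {
  assert_rhd_label(label); assert_channel(channel)
  if (!is.null(seed)) return(with_seed(seed, simulate_image(
    label, channel, geometry, intensity, noise, n_bf, n_fluo, psf_sigma_px,
    edge_clip_fraction, min_sep_factor, peak_min_sep_px, bf_levels,
    bf_noise_sd, seed = NULL)))
  if (is.null(intensity)) intensity <- default_intensity_models()[[channel]][[label]]
  stopifnot(inherits(geometry, "rhd_geometry"), inherits(noise, "rhd_noise_model"),
            inherits(intensity, "rhd_intensity_model"), n_fluo >= 1,
            min_sep_factor >= 1.5)
  H <- geometry$height_px; W <- geometry$width_px
  rbar <- geometry$cell_radius_mean_px
  if (min(H, W) < 2 * (rbar + 4))
    stop("geometry too small to place one cell of mean radius ", rbar)

  # ---- place cells ----------------------------------------------------
  n_cells <- rpois(1, geometry$cells_per_image_rate)
  centers <- matrix(numeric(0), 0, 2)
  radii <- numeric(0); clipped <- logical(0)
  min_sep <- min_sep_factor * rbar
  for (k in seq_len(n_cells)) {
    r <- max(0.6 * rbar, min(1.4 * rbar,
             rnorm(1, rbar, geometry$cell_radius_sd_px)))
    clip <- runif(1) < edge_clip_fraction
    placed <- FALSE
    for (att in 1:200) {
      if (clip) {
        side <- sample.int(4, 1)
        off <- runif(1, -0.3, 0.6) * r   # centre near the border
        pos <- switch(side,
          c(1 + off, runif(1, 1, W)),            # top
          c(H - off, runif(1, 1, W)),            # bottom
          c(runif(1, 1, H), 1 + off),            # left
          c(runif(1, 1, H), W - off))            # right
      } else {
        pos <- c(runif(1, r + 3, H - r - 2), runif(1, r + 3, W - r - 2))
      }
      if (nrow(centers) == 0 ||
          all(sqrt((centers[, 1] - pos[1])^2 + (centers[, 2] - pos[2])^2) >= min_sep)) {
        centers <- rbind(centers, pos); radii <- c(radii, r)
        clipped <- c(clipped, clip); placed <- TRUE
        break
      }
    }
    if (!placed) next
  }
  n_cells <- nrow(centers)
  touches <- logical(n_cells)
  if (n_cells > 0)
    touches <- centers[, 1] - radii < 1 | centers[, 1] + radii > H |
               centers[, 2] - radii < 1 | centers[, 2] + radii > W

  # ---- draw peaks -----------------------------------------------------
  labelled <- if (n_cells > 0) runif(n_cells) < intensity$labelled_fraction else logical(0)
  bg <- noise$background_mean
  floor_T <- 9 * bg + 3 * noise$background_sd
  pk_cell <- integer(0); pk_r <- numeric(0); pk_c <- numeric(0)
  for (k in seq_len(n_cells)) {
    if (!labelled[k]) next
    npk <- max(intensity$min_peaks_if_labelled,
               rpois(1, intensity$peaks_per_labelled_cell_rate))
    for (p in seq_len(npk)) {
      for (att in 1:60) {
        rad <- 0.85 * radii[k] * sqrt(runif(1))
        ang <- runif(1, 0, 2 * pi)
        pr <- centers[k, 1] + rad * sin(ang)
        pc <- centers[k, 2] + rad * cos(ang)
        if (round(pr) < 2 || round(pr) > H - 1 || round(pc) < 2 || round(pc) > W - 1)
          next
        if (length(pk_r) == 0 ||
            all((pk_r - pr)^2 + (pk_c - pc)^2 >= peak_min_sep_px^2)) {
          pk_cell <- c(pk_cell, k); pk_r <- c(pk_r, pr); pk_c <- c(pk_c, pc)
          break
        }
      }
    }
  }
  npk <- length(pk_r)
  if (npk > 0) {
    plo <- pnorm(floor_T, intensity$mean_peak_intensity, intensity$sd_peak_intensity)
    if (plo > 0.999) stop("truncation bound exceeds the intensity distribution")
    u <- runif(npk, plo, 1)
    target <- qnorm(u, intensity$mean_peak_intensity, intensity$sd_peak_intensity)
    # amplitudes solve the full coupling system: peak j's PSF bleeds
    # into peak i's 3x3 window, so M A = target - 9 bg with
    # M[i, j] = sum of peak j's unit PSF over window i. This keeps the
    # expected measured 3x3 sums equal to the drawn targets at any
    # peak density.
    ri <- round(pk_r); ci <- round(pk_c)
    M <- matrix(0, npk, npk)
    for (dx in -1:1) for (dy in -1:1) {
      dr <- outer(ri + dx, pk_r, "-")
      dc <- outer(ci + dy, pk_c, "-")
      M <- M + exp(-(dr^2 + dc^2) / (2 * psf_sigma_px^2))
    }
    amp <- as.vector(solve(M, target - 9 * bg))
    bad <- amp <= 0   # extreme clusters: fall back to the isolated solve
    if (any(bad))
      amp[bad] <- (target[bad] - 9 * bg) /
        psf_3x3_factor(pk_r[bad] - ri[bad], pk_c[bad] - ci[bad], psf_sigma_px)
  } else {
    target <- numeric(0); amp <- numeric(0)
  }

  # ---- render frames --------------------------------------------------
  signal <- matrix(0, H, W)
  if (npk > 0)
    signal <- render_spots_cpp(signal, pk_r - 1, pk_c - 1, amp, psf_sigma_px)
  noise_sd_px <- sqrt(noise$background_sd^2 +
                      if (noise$shot_noise) signal / noise$photons_per_count else 0)
  bf_base <- matrix(bf_levels[["background"]], H, W)
  for (k in seq_len(n_cells)) {
    r <- radii[k]
    i0 <- max(1, floor(centers[k, 1] - r)); i1 <- min(H, ceiling(centers[k, 1] + r))
    j0 <- max(1, floor(centers[k, 2] - r)); j1 <- min(W, ceiling(centers[k, 2] + r))
    ii <- i0:i1; jj <- j0:j1
    d <- sqrt(outer((ii - centers[k, 1])^2, (jj - centers[k, 2])^2, "+"))
    patch <- bf_base[ii, jj]
    patch[d <= r] <- bf_levels[["rim"]]
    patch[d <= r - 2] <- bf_levels[["interior"]]
    bf_base[ii, jj] <- patch
  }
  clamp16 <- function(m) {
    m <- round(m); m[m < 0] <- 0; m[m > 65535] <- 65535; m
  }
  frames <- vector("list", n_bf + n_fluo)
  for (f in seq_len(n_bf))
    frames[[f]] <- clamp16(bf_base + matrix(rnorm(H * W, 0, bf_noise_sd), H, W))
  for (f in seq_len(n_fluo))
    frames[[n_bf + f]] <- clamp16(signal + bg +
                                  matrix(rnorm(H * W), H, W) * noise_sd_px)
  stack <- structure(list(frames = frames,
                          modality = c(rep("BF", n_bf), rep("FLUO", n_fluo)),
                          pixel_pitch_um = geometry$pixel_pitch_um),
                     class = "rhd_stack")
  cells <- data.frame(cell_id = seq_len(n_cells) - 1L,
                      center_row = if (n_cells) centers[, 1] else numeric(0),
                      center_col = if (n_cells) centers[, 2] else numeric(0),
                      radius = radii, touches_edge = touches,
                      is_labelled = labelled, row.names = NULL)
  peaks <- data.frame(cell_id = pk_cell - 1L,
                      row = as.integer(round(pk_r)), col = as.integer(round(pk_c)),
                      true_3x3_sum = target, row.names = NULL)
  list(stack = stack, truth = list(cells = cells, peaks = peaks))
}

#' Simulate all images of one manifest entry
#'
#' Deterministic in the entry's `seed`: repeated calls return
#' bitwise-identical stacks and ground truth.
#'
#' @param entry one row of a manifest ([build_default_manifest()]) as a
#'   list or single-row data.frame.
#' @param geometry,models,noise simulation models; `models` is the
#'   nested list of [default_intensity_models()].
#' @param ... further arguments passed to [simulate_image()]
#'   (e.g. `n_bf`, `n_fluo`).
#' @return list with `sample_id`, `label`, `channel`, and `images`, a
#'   list of `simulate_image()` results.
#' @export
simulate_sample <- function(entry, geometry = field_geometry(),
                            models = default_intensity_models(),
                            noise = noise_model(), ...) {
  entry <- as.list(entry)
  stopifnot(!is.null(entry$sample_id), entry$images_per_sample >= 1)
  assert_rhd_label(entry$label); assert_channel(entry$channel)
  intensity <- models[[entry$channel]][[entry$label]]
  images <- with_seed(entry$seed, lapply(seq_len(entry$images_per_sample),
    function(i) simulate_image(entry$label, entry$channel, geometry,
                               intensity, noise, ...)))
  list(sample_id = entry$sample_id, label = entry$label,
       channel = entry$channel, images = images)
}
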