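#' Spot-detection parameters
#'
#' Single-molecule peaks are found by conservative smoothing (clamping
#' each pixel to the min/max of its neighbourhood), white top-hat
#' filtering with a disk structuring element, thresholding, and region
#' growing. Background statistics are taken from the lower three
#' quartiles of the top-hat image: cells and peaks occupy a large area
#' fraction, and robust statistics keep them from inflating the
#' threshold.
#'
#' @param conservative_smoothing_radius_px smoothing neighbourhood
#'   radius.
#' @param tophat_disk_radius_px disk structuring element radius.
#' @param threshold_k seed threshold, in background SDs above the
#'   background mean.
#' @param region_grow_low_k region-growing (secondary) threshold
#'   multiple; must be below `threshold_k`.
#' @param min_region_px,max_region_px accepted region size range.
#' @param min_peak_separation_px peaks closer than this are merged,
#'   keeping the brighter.
#' @return object of class `rhd_spot_params`.
#' @export
spot_params <- function(conservative_smoothing_radius_px = 1,
                        tophat_disk_radius_px = 3,
                        threshold_k = 5, region_grow_low_k = 2,
                        min_region_px = 2, max_region_px = 50,
                        min_peak_separation_px = 2) {
  stopifnot(conservative_smoothing_radius_px >= 1,
            tophat_disk_radius_px >= 1,
            threshold_k > region_grow_low_k, region_grow_low_k >= 0,
            min_region_px >= 1, max_region_px >= min_region_px)
  structure(as.list(environment()), class = "rhd_spot_params")
}

#' Sum of the 3x3 pixel window centred on a peak maximum
#'
#' This is the peak intensity quantification used throughout: the sum of
#' the nine pixel values around the maximum. Indices are 1-based (R
#' convention; exported CSVs are 0-based).
#'
#' @param frame numeric matrix.
#' @param row,col centre pixel, with `2 <= row <= nrow - 1` and
#'   `2 <= col <= ncol - 1`.
#' @return the 9-pixel sum, in counts.
#' @export
peak_intensity <- function(frame, row, col) {
  H <- nrow(frame); W <- ncol(frame)
  if (any(row < 2 | row > H - 1 | col < 2 | col > W - 1))
    stop("3x3 window off frame for peak at (", row[1], ", ", col[1], ")")
  vapply(seq_along(row), function(k)
    sum(frame[(row[k] - 1):(row[k] + 1), (col[k] - 1):(col[k] + 1)]),
    numeric(1))
}

#' Detect single-molecule fluorescence peaks
#'
#' @param fluo_frame numeric matrix (fluorescence modality).
#' @param params [spot_params()].
#' @return data.frame with one row per peak: `peak_id`, `row`, `col`
#'   (1-based pixel of the maximum, at least 1 px from every border),
#'   `intensity_counts` (3x3 sum on the original frame), `cell_id`
#'   (`NA` until [assign_peaks()]), `excluded`.
#' @export
detect_peaks <- function(fluo_frame, params = spot_params()) {
  if (!is.matrix(fluo_frame)) stop("fluo_frame must be a 2-D matrix")
  H <- nrow(fluo_frame); W <- ncol(fluo_frame)
  sm <- conservative_smooth_cpp(fluo_frame,
                                as.integer(params$conservative_smoothing_radius_px))
  open <- dilate_disk_cpp(erode_disk_cpp(sm, as.integer(params$tophat_disk_radius_px)),
                          as.integer(params$tophat_disk_radius_px))
  th <- sm - open
  # background statistics from the lower three quartiles of the top-hat
  # image: median as mean, IQR/1.349 as SD (a subset SD would be biased
  # low and flood the threshold with false positives)
  q <- quantile(th, c(0.25, 0.5, 0.75), names = FALSE)
  bg_mean <- q[2]; bg_sd <- (q[3] - q[1]) / 1.349
  if (bg_sd <= 0) bg_sd <- max(mad(th), 1e-8)
  thr <- bg_mean + params$threshold_k * bg_sd
  low <- bg_mean + params$region_grow_low_k * bg_sd
  empty <- data.frame(peak_id = integer(0), row = integer(0), col = integer(0),
                      intensity_counts = numeric(0), cell_id = integer(0),
                      excluded = logical(0))
  # super-threshold local maxima seed the region growing; regions grow
  # down to the low level but never merge across seeds
  seeds <- local_maxima_cpp(th, thr, params$min_peak_separation_px)
  if (nrow(seeds) == 0) return(empty)
  lab <- region_grow_cpp(th, as.integer(seeds[, 1]), as.integer(seeds[, 2]), low)
  idx <- which(lab > 0)
  regs <- split(idx, lab[idx])
  rows <- integer(0); cols <- integer(0)
  for (px in regs) {
    if (length(px) < params$min_region_px || length(px) > params$max_region_px)
      next
    bright <- px[which.max(fluo_frame[px])]     # maximum of ORIGINAL frame
    r <- ((bright - 1) %% H) + 1
    c <- ((bright - 1) %/% H) + 1
    if (r < 2 || r > H - 1 || c < 2 || c > W - 1) next  # 3x3 undefined
    rows <- c(rows, r); cols <- c(cols, c)
  }
  if (length(rows) == 0) return(empty)
  if (length(rows) == 0) return(empty)
  # merge peaks closer than the separation limit, keeping the brighter
  val <- fluo_frame[cbind(rows, cols)]
  ord <- order(-val, rows, cols)
  keep <- integer(0)
  for (k in ord) {
    if (length(keep) == 0 ||
        all((rows[keep] - rows[k])^2 + (cols[keep] - cols[k])^2 >=
            params$min_peak_separation_px^2))
      keep <- c(keep, k)
  }
  keep <- keep[order(rows[keep], cols[keep])]
  data.frame(peak_id = seq_along(keep) - 1L,
             row = rows[keep], col = cols[keep],
             intensity_counts = peak_intensity(fluo_frame, rows[keep], cols[keep]),
             cell_id = NA_integer_, excluded = FALSE, row.names = NULL)
}

#' Assign detected peaks to cell contours
#'
#' A peak belongs to the contour whose mask contains its maximum; if
#' masks overlap at that pixel the contour with the nearest centroid
#' wins (deterministic). Unassigned peaks and peaks on edge-flagged cells
#' are retained but marked `excluded` so feature extraction skips them.
#'
#' @param peaks data.frame from [detect_peaks()].
#' @param contours list of `rhd_contour` from [detect_cells()].
#' @return `peaks` with `cell_id` and `excluded` filled in.
#' @export
assign_peaks <- function(peaks, contours) {
  if (nrow(peaks) == 0) return(peaks)
  edge_ids <- vapply(contours, function(ct) ct$touches_edge, logical(1))
  for (k in seq_len(nrow(peaks))) {
    hits <- which(vapply(contours, function(ct)
      ct$mask[peaks$row[k], peaks$col[k]], logical(1)))
    if (length(hits) == 0) {
      peaks$cell_id[k] <- NA_integer_
      peaks$excluded[k] <- TRUE
    } else {
      if (length(hits) > 1) {
        d <- vapply(hits, function(h)
          sum((contours[[h]]$centroid - c(peaks$row[k], peaks$col[k]))^2),
          numeric(1))
        hits <- hits[which.min(d)]
      }
      peaks$cell_id[k] <- contours[[hits]]$cell_id
      peaks$excluded[k] <- edge_ids[hits]
    }
  }
  peaks
}

#' Per-peak and summary signal-to-noise ratio
#'
#' SNR is `(peak maximum - local background median) / background SD`.
#' The background level is local: the sigma-clipped median of an annulus
#' `annulus[1]`-`annulus[2]` px around the peak. The noise SD is the
#' robust (1.4826 MAD) SD of the whole frame: single-molecule spots
#' cover a few percent of the pixels at most, so the frame MAD estimates
#' the camera noise, whereas at high per-cell peak densities the annulus
#' is majority signal and any local spread estimate is inflated by
#' neighbouring peaks.
#'
#' @param frame numeric matrix the peaks were detected on.
#' @param peaks data.frame with `row`, `col` (1-based).
#' @param annulus inner/outer annulus radii, pixels.
#' @param background_sd optional known noise SD (e.g. from a camera
#'   calibration); when given it replaces the frame-MAD estimate.
#' @return list with `per_peak` (numeric vector), `mean`, `sd`.
#' @export
estimate_snr <- function(frame, peaks, annulus = c(5, 8),
                         background_sd = NULL) {
  if (nrow(peaks) == 0) stop("estimate_snr needs at least one peak")
  H <- nrow(frame); W <- ncol(frame)
  ro <- annulus[2]
  d2 <- outer((-ro:ro)^2, (-ro:ro)^2, "+")
  ring <- d2 >= annulus[1]^2 & d2 <= annulus[2]^2
  ridx <- which(ring, arr.ind = TRUE)
  s <- if (!is.null(background_sd)) background_sd else mad(frame)
  if (is.na(s) || s == 0) stop("zero background SD in frame")
  snr <- vapply(seq_len(nrow(peaks)), function(k) {
    i0 <- peaks$row[k] - ro; j0 <- peaks$col[k] - ro
    ii <- pmin(pmax(i0 + ridx[, 1] - 1, 1), H)
    jj <- pmin(pmax(j0 + ridx[, 2] - 1, 1), W)
    bg <- frame[cbind(ii, jj)]
    # sigma-clip away neighbouring peaks bleeding into the annulus
    for (it in 1:2) bg <- bg[bg <= median(bg) + 3 * mad(bg)]
    (frame[peaks$row[k], peaks$col[k]] - median(bg)) / s
  }, numeric(1))
  list(per_peak = snr, mean = mean(snr), sd = sd(snr))
}

#' Write detected peaks to CSV (0-based coordinates)
#'
#' @param peaks data.frame from [assign_peaks()].
#' @param image_id identifier recorded with every row.
#' @param path output CSV.
#' @export
write_peaks <- function(peaks, image_id, path) {
  out <- data.frame(image_id = image_id, peak_id = peaks$peak_id,
                    row = peaks$row - 1L, col = peaks$col - 1L,
                    intensity_counts = peaks$intensity_counts,
                    cell_id = peaks$cell_id, excluded_flag = peaks$excluded)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
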