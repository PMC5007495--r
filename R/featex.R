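feature_names <- function() c("number_of_peaks", "cell_intensity",
                              "sd_cell_intensity", "peak_density",
                              "distance_complete", "distance_nearest",
                              "intensity_ratio")

#' Per-cell statistics of the peaks on one erythrocyte
#'
#' @param contour non-edge `rhd_contour`.
#' @param peaks data.frame of the peaks assigned to this cell.
#' @param pixel_pitch_um object-space pixel pitch, um/pixel.
#' @return list: `cell_id`, `n_peaks`, `mean_peak_intensity` (`NA` when
#'   no peaks), `area_um2`, `mean_pairwise_distance_um` and
#'   `mean_nearest_distance_um` (`NA` unless at least two peaks).
#' @export
cell_features <- function(contour, peaks, pixel_pitch_um) {
  stopifnot(inherits(contour, "rhd_contour"))
  if (contour$touches_edge)
    stop("cell_features called on an edge-flagged cell (cell_id ",
         contour$cell_id, "); edge cells must be filtered upstream")
  n <- nrow(peaks)
  mp <- if (n >= 1) mean(peaks$intensity_counts) else NA_real_
  pw <- nn <- NA_real_
  if (n >= 2) {
    d <- as.matrix(dist(cbind(peaks$row, peaks$col))) * pixel_pitch_um
    pw <- mean(d[upper.tri(d)])
    diag(d) <- Inf
    nn <- mean(apply(d, 1, min))
  }
  list(cell_id = contour$cell_id, n_peaks = n, mean_peak_intensity = mp,
       area_um2 = contour$area_px * pixel_pitch_um^2,
       mean_pairwise_distance_um = pw, mean_nearest_distance_um = nn)
}

#' Image-level feature vector (the seven classification features)
#'
#' Edge-flagged cells and their peaks, and unassigned peaks, are
#' excluded. `number_of_peaks` is the mean peak count per (non-edge)
#' cell; `cell_intensity` and `sd_cell_intensity` are the mean and SD
#' across cells-with-signal of the per-cell mean peak intensity;
#' `peak_density` is the mean per-cell `n_peaks / area_um2`; the two
#' distance features average the per-cell pairwise and nearest-neighbour
#' peak distances over cells with at least two peaks (0 when no such
#' cell); `intensity_ratio` is the mean fluorescence pixel value inside
#' the union of non-edge masks over the mean outside all masks.
#' Undefined intensity values are encoded as 0 with `has_signal = FALSE`
#' so classifier inputs stay complete.
#'
#' @param contours all contours of the field (edge flags set).
#' @param peaks assigned peaks ([assign_peaks()]).
#' @param fluo_frame the fluorescence frame the peaks came from.
#' @param pixel_pitch_um um/pixel.
#' @return one-row data.frame: the seven features plus `n_cells`,
#'   `has_signal` and the auxiliary raw `total_peaks` (not used for
#'   classification).
#' @export
image_features <- function(contours, peaks, fluo_frame, pixel_pitch_um) {
  edge <- vapply(contours, function(ct) ct$touches_edge, logical(1))
  keep <- contours[!edge]
  if (length(keep) == 0) {
    cond <- structure(class = c("rhd_empty_image", "error", "condition"),
                      list(message = "no non-edge cells in image", call = NULL))
    stop(cond)
  }
  pk <- peaks[!peaks$excluded & !is.na(peaks$cell_id), , drop = FALSE]
  cf <- lapply(keep, function(ct)
    cell_features(ct, pk[pk$cell_id == ct$cell_id, , drop = FALSE],
                  pixel_pitch_um))
  npk <- vapply(cf, function(x) x$n_peaks, numeric(1))
  mpi <- vapply(cf, function(x) x$mean_peak_intensity, numeric(1))
  area <- vapply(cf, function(x) x$area_um2, numeric(1))
  pwd <- vapply(cf, function(x) x$mean_pairwise_distance_um, numeric(1))
  nnd <- vapply(cf, function(x) x$mean_nearest_distance_um, numeric(1))
  with_sig <- !is.na(mpi)
  has_signal <- any(with_sig)
  cell_intensity <- if (has_signal) mean(mpi[with_sig]) else 0
  sd_ci <- if (sum(with_sig) >= 2) sd(mpi[with_sig]) else 0
  dc <- if (any(!is.na(pwd))) mean(pwd, na.rm = TRUE) else 0
  dn <- if (any(!is.na(nnd))) mean(nnd, na.rm = TRUE) else 0
  inside <- Reduce(`|`, lapply(keep, function(ct) ct$mask))
  all_masks <- Reduce(`|`, lapply(contours, function(ct) ct$mask))
  outside <- !all_masks
  ratio <- if (any(outside) && mean(fluo_frame[outside]) > 0)
    mean(fluo_frame[inside]) / mean(fluo_frame[outside]) else 0
  data.frame(number_of_peaks = mean(npk),
             cell_intensity = cell_intensity,
             sd_cell_intensity = sd_ci,
             peak_density = mean(npk / area),
             distance_complete = dc,
             distance_nearest = dn,
             intensity_ratio = ratio,
             n_cells = length(keep),
             has_signal = has_signal,
             total_peaks = sum(npk))
}

#' Sample-level feature vector: per-feature means over a sample's images
#'
#' @param images data.frame of image feature vectors (rows = images).
#' @return one-row data.frame of the seven feature means plus
#'   `n_images`.
#' @export
sample_features <- function(images) {
  if (is.null(images) || nrow(images) == 0)
    stop("sample_features needs at least one image feature vector")
  out <- as.data.frame(as.list(colMeans(images[, feature_names(), drop = FALSE])))
  out$n_images <- nrow(images)
  out
}
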