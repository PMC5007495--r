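#' Pipeline configuration
#'
#' A plain nested list of constructor arguments for every stage, so the
#' whole configuration round-trips losslessly through JSON
#' ([write_config()] / [read_config()]). Fields left empty use the
#' stage defaults.
#'
#' @param geometry,noise,segmentation,spots argument lists for
#'   [field_geometry()], [noise_model()], [segmentation_params()],
#'   [spot_params()].
#' @param cv argument list for [cv_config()] (its `gp` entry, if any, is
#'   an argument list for [gp_config()]).
#' @param simulate argument list: `n_bf`, `n_fluo`, `images_range`,
#'   `channel`, plus any [simulate_image()] rendering option.
#' @param decider list with `image_count_threshold`.
#' @param seed root seed; all stage streams derive from it.
#' @return object of class `rhd_pipeline_config`.
#' @export
pipeline_config <- function(geometry = list(), noise = list(),
                            segmentation = list(), spots = list(),
                            cv = list(), simulate = list(n_bf = 1, n_fluo = 1),
                            decider = list(image_count_threshold = 11),
                            seed = 1L) {
  structure(list(geometry = geometry, noise = noise,
                 segmentation = segmentation, spots = spots, cv = cv,
                 simulate = simulate, decider = decider,
                 seed = as.integer(seed)),
            class = "rhd_pipeline_config")
}

#' @rdname pipeline_config
#' @param config an `rhd_pipeline_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, x)
}

build_stage_params <- function(config) {
  geometry <- do.call(field_geometry, config$geometry)
  seg_args <- config$segmentation
  if (is.null(seg_args$cell_radius_mean_px))
    seg_args$cell_radius_mean_px <- geometry$cell_radius_mean_px
  cv_args <- config$cv
  if (!is.null(cv_args$gp)) cv_args$gp <- do.call(gp_config, as.list(cv_args$gp))
  list(geometry = geometry,
       noise = do.call(noise_model, config$noise),
       seg = do.call(segmentation_params, seg_args),
       spot = do.call(spot_params, config$spots),
       cv = do.call(cv_config, cv_args))
}

#' Segment, detect and featurise one image stack
#'
#' Consumes the first bright-field and the first fluorescence frame of
#' the stack: segments cells, detects and assigns peaks, and computes
#' the image feature vector.
#'
#' @param stack an `rhd_stack`.
#' @param seg_params,spot_params stage parameters.
#' @return list with `contours`, `peaks`, `features` (`NULL` when the
#'   image has no usable cell) and `reason` (`NA` or the skip reason).
#' @export
process_stack <- function(stack, seg_params = segmentation_params(),
                          spot_params_ = spot_params()) {
  stopifnot(inherits(stack, "rhd_stack"))
  bf_i <- which(stack$modality == "BF")[1]
  fl_i <- which(stack$modality == "FLUO")[1]
  if (is.na(bf_i) || is.na(fl_i))
    stop("stack must contain at least one bright-field and one fluorescence frame")
  contours <- detect_cells(stack$frames[[bf_i]], seg_params)
  peaks <- detect_peaks(stack$frames[[fl_i]], spot_params_)
  peaks <- assign_peaks(peaks, contours)
  feats <- tryCatch(
    image_features(contours, peaks, stack$frames[[fl_i]], stack$pixel_pitch_um),
    rhd_empty_image = function(e) conditionMessage(e))
  if (is.character(feats))
    list(contours = contours, peaks = peaks, features = NULL, reason = feats)
  else
    list(contours = contours, peaks = peaks, features = feats,
         reason = NA_character_)
}

#' Run the full synthetic-cohort pipeline
#'
#' Simulates every manifest sample, processes each image (segmentation,
#' peak detection and assignment, feature extraction), builds the image-
#' and sample-level feature tables and classifies the cohort with
#' Methods 1, 2 and the rule-based fusion. Fully reproducible from
#' `(config, manifest)`; images without usable cells are skipped and
#' samples with no usable image are excluded, both with a logged reason
#' (messages to standard error).
#'
#' @param config [pipeline_config()].
#' @param manifest cohort manifest; default
#'   `build_default_manifest(config$seed, ...)`.
#' @param out_dir optional directory: persists feature tables, votes,
#'   assignments and the confusion matrix as CSV stamped with the
#'   config hash and seed.
#' @param verbose emit per-sample progress messages.
#' @return list: `image_features`, `sample_features`, `result`
#'   ([classify_cohort()] output), `skipped` (data.frame of skipped
#'   items), `manifest`, `config_hash`.
#' @export
run_pipeline <- function(config = pipeline_config(), manifest = NULL,
                         out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "rhd_pipeline_config"))
  p <- build_stage_params(config)
  sim_args <- config$simulate
  if (is.null(manifest)) {
    mr <- sim_args$images_range
    if (is.null(mr)) mr <- c(11L, 15L)
    manifest <- build_default_manifest(config$seed, images_range = mr,
      channel = if (is.null(sim_args$channel)) "H41" else sim_args$channel)
  }
  sim_args$images_range <- NULL; sim_args$channel <- NULL
  models <- default_intensity_models()
  image_rows <- list(); skipped <- list()
  for (si in seq_len(nrow(manifest))) {
    entry <- manifest[si, ]
    if (verbose) message("sample ", entry$sample_id, " (", entry$label, ")")
    sample <- tryCatch(
      do.call(simulate_sample,
              c(list(entry = entry, geometry = p$geometry, models = models,
                     noise = p$noise), sim_args)),
      error = function(e) stop("stage simulate failed for sample ",
                               entry$sample_id, ": ", conditionMessage(e)))
    for (ii in seq_along(sample$images)) {
      res <- tryCatch(
        process_stack(sample$images[[ii]]$stack, p$seg, p$spot),
        error = function(e) stop("stage process failed for ",
                                 entry$sample_id, " image ", ii, ": ",
                                 conditionMessage(e)))
      if (is.null(res$features)) {
        message("skipping ", entry$sample_id, " image ", ii, ": ", res$reason)
        skipped[[length(skipped) + 1]] <- data.frame(
          sample_id = entry$sample_id, image = ii, reason = res$reason)
        next
      }
      image_rows[[length(image_rows) + 1]] <- cbind(
        data.frame(item_id = paste0(entry$sample_id, "/", ii),
                   sample_id = entry$sample_id, label = entry$label),
        res$features)
    }
  }
  image_table <- do.call(rbind, image_rows)
  counts <- table(image_table$sample_id)
  lost <- setdiff(manifest$sample_id, names(counts))
  for (s in lost) message("excluding sample ", s, ": no usable images")
  sample_table <- do.call(rbind, lapply(names(counts), function(s) {
    rows <- image_table[image_table$sample_id == s, , drop = FALSE]
    cbind(data.frame(item_id = s, sample_id = s, label = rows$label[1]),
          sample_features(rows))
  }))
  result <- classify_cohort(image_table, sample_table, p$cv,
                            config$decider$image_count_threshold)
  hash <- config_hash(unclass(config))
  out <- list(image_features = image_table, sample_features = sample_table,
              result = result,
              skipped = if (length(skipped)) do.call(rbind, skipped) else NULL,
              manifest = manifest, config_hash = hash)
  if (!is.null(out_dir)) persist_pipeline(out, config, out_dir)
  out
}

persist_pipeline <- function(out, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- function(df) {
    df$config_hash <- out$config_hash
    df$seed <- config$seed
    df
  }
  write.csv(stamp(out$image_features),
            file.path(out_dir, "image_features.csv"), row.names = FALSE)
  write.csv(stamp(out$sample_features),
            file.path(out_dir, "sample_features.csv"), row.names = FALSE)
  write.csv(stamp(out$result$assignments),
            file.path(out_dir, "final_assignments.csv"), row.names = FALSE)
  write.csv(stamp(out$result$m1), file.path(out_dir, "method1_votes.csv"),
            row.names = FALSE)
  write.csv(stamp(out$result$m2), file.path(out_dir, "method2_votes.csv"),
            row.names = FALSE)
  if (!is.null(out$result$confusion))
    write.csv(as.data.frame(out$result$confusion),
              file.path(out_dir, "confusion_matrix.csv"))
  write_manifest(out$manifest, file.path(out_dir, "manifest.csv"))
  write_config(config, file.path(out_dir, "config.json"))
  invisible(out_dir)
}
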