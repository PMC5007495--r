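#' Build the default 51-sample cohort manifest
#'
#' Mirrors the published cohort: 12 D+, 14 weak D (6 + 3 + 5 across the
#' three weak D alleles), 12 DEL (6 + 6), and 13 D- samples. Each sample
#' gets an image count drawn uniformly from `images_range` (default
#' 11-15, so both branches of the >= 11 image-count decision rule occur
#' in a default cohort) and a per-sample seed derived from `seed`.
#'
#' @param seed integer root seed.
#' @param images_range integer length-2 range for images per sample.
#' @param class_counts named integer vector of samples per class.
#' @param channel antibody channel for the cohort.
#' @return data.frame with columns `sample_id`, `label`, `channel`,
#'   `images_per_sample`, `seed`.
#' @export
build_default_manifest <- function(seed = 0L, images_range = c(11L, 15L),
                                   class_counts = c(D_POS = 12L, WEAK_D = 14L,
                                                    DEL = 12L, D_NEG = 13L),
                                   channel = "H41") {
  assert_rhd_label(names(class_counts))
  assert_channel(channel)
  stopifnot(length(images_range) == 2, images_range[1] >= 1,
            images_range[2] >= images_range[1], all(class_counts >= 1))
  labels <- rep(names(class_counts), class_counts)
  n <- length(labels)
  ids <- sprintf("S%02d", seq_len(n))
  span <- images_range[2] - images_range[1] + 1L
  n_img <- with_seed(derive_seed(seed, "manifest"),
                     images_range[1] + sample.int(span, n, replace = TRUE) - 1L)
  data.frame(sample_id = ids, label = labels, channel = channel,
             images_per_sample = as.integer(n_img),
             seed = vapply(ids, function(id) derive_seed(seed, paste0("sample/", id)),
                           integer(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write / read a cohort manifest as delimited text
#'
#' @param manifest data.frame as returned by [build_default_manifest()].
#' @param path file path.
#' @return `read_manifest` returns the manifest data.frame.
#' @export
write_manifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "label", "channel", "images_per_sample", "seed")
  if (!all(need %in% names(m)))
    stop("manifest ", path, " lacks columns: ",
         paste(setdiff(need, names(m)), collapse = ", "))
  assert_rhd_label(m$label)
  m
}
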