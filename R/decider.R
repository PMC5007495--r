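#' Fuse image-level and sample-level labels into the final assignment
#'
#' The decision rules, applied in order:
#' 1. concordant labels are kept (`CONCORDANT`);
#' 2. when the two methods disagree between D- and DEL (the two most
#'    similar classes) the image-level result is trusted if the sample
#'    has at least `image_count_threshold` images
#'    (`DNEG_DEL_IMAGES_GE_11`), otherwise the sample-level result
#'    (`DNEG_DEL_IMAGES_LT_11`);
#' 3. a weak D vs DEL disagreement always takes the image-level result
#'    (`WEAKD_DEL_IMAGE_LEVEL`), which carries more cell-population
#'    heterogeneity information;
#' 4. in any other case the sample-level result wins
#'    (`DEFAULT_SAMPLE_LEVEL`).
#'
#' The D-/DEL rule is symmetric in the unordered label pair, so it never
#' falls through to rule 3. The function is total and deterministic and
#' the final label always equals one of the two inputs.
#'
#' @param m1_label,m2_label image-level and sample-level labels
#'   (vectorised).
#' @param n_images images acquired for the sample (>= 1).
#' @param image_count_threshold rule-2 threshold (default 11).
#' @return data.frame with `label`, `m1_label`, `m2_label`, `n_images`,
#'   `rule_fired`.
#' @export
combine_methods <- function(m1_label, m2_label, n_images,
                            image_count_threshold = 11) {
  assert_rhd_label(m1_label); assert_rhd_label(m2_label)
  stopifnot(all(n_images >= 1))
  n <- length(m1_label)
  label <- character(n); rule <- character(n)
  for (i in seq_len(n)) {
    pair <- c(m1_label[i], m2_label[i])
    if (pair[1] == pair[2]) {
      label[i] <- pair[1]; rule[i] <- "CONCORDANT"
    } else if (setequal(pair, c("D_NEG", "DEL"))) {
      if (n_images[i] >= image_count_threshold) {
        label[i] <- m1_label[i]; rule[i] <- "DNEG_DEL_IMAGES_GE_11"
      } else {
        label[i] <- m2_label[i]; rule[i] <- "DNEG_DEL_IMAGES_LT_11"
      }
    } else if (setequal(pair, c("WEAK_D", "DEL"))) {
      label[i] <- m1_label[i]; rule[i] <- "WEAKD_DEL_IMAGE_LEVEL"
    } else {
      label[i] <- m2_label[i]; rule[i] <- "DEFAULT_SAMPLE_LEVEL"
    }
  }
  data.frame(label = label, m1_label = m1_label, m2_label = m2_label,
             n_images = n_images, rule_fired = rule,
             stringsAsFactors = FALSE)
}

#' Confusion matrix in the standard reporting layout
#'
#' Rows are predicted classes, columns actual classes; entries are
#' percentages of each actual class (columns sum to 100 for classes
#' that occur).
#'
#' @param predicted,actual RhD label vectors of equal length.
#' @return 4 x 4 numeric matrix of per-column percentages.
#' @export
confusion_matrix_rhd <- function(predicted, actual) {
  assert_rhd_label(predicted); assert_rhd_label(actual)
  lv <- rhd_labels()
  m <- table(factor(predicted, lv), factor(actual, lv))
  cs <- colSums(m)
  pct <- sweep(m, 2, pmax(cs, 1), "/") * 100
  unclass(pct)
}

#' Classify a cohort end to end (Methods 1 + 2 + rule fusion)
#'
#' Runs image-level and sample-level classification independently and
#' fuses the two per-sample labels with [combine_methods()].
#'
#' @param image_table image-level feature table.
#' @param sample_table sample-level feature table (same sample set).
#' @param cfg [cv_config()].
#' @param image_count_threshold rule-2 threshold.
#' @return list: `assignments` (one row per sample: `sample_id`, final
#'   `label`, `m1_label`, `m2_label`, `n_images`, `rule_fired`, and
#'   `actual` when the tables carry labels), `m1`, `m2`, `confusion`
#'   (predicted x actual percentages) and `accuracy`.
#' @export
classify_cohort <- function(image_table, sample_table, cfg = cv_config(),
                            image_count_threshold = 11) {
  if (!setequal(image_table$sample_id, sample_table$sample_id))
    stop("image and sample tables cover different samples: ",
         paste(union(setdiff(image_table$sample_id, sample_table$sample_id),
                     setdiff(sample_table$sample_id, image_table$sample_id)),
               collapse = ", "))
  m1 <- classify_method1(image_table, cfg)
  m2 <- classify_method2(sample_table, cfg)
  ord <- match(m1$sample_id, m2$sample_id)
  comb <- combine_methods(m1$label, m2$label[ord], m1$n_items,
                          image_count_threshold)
  assignments <- data.frame(sample_id = m1$sample_id, comb,
                            stringsAsFactors = FALSE)
  actual <- sample_table$label[match(assignments$sample_id,
                                     sample_table$sample_id)]
  confusion <- NULL; accuracy <- NA_real_
  if (!is.null(actual) && all(!is.na(actual))) {
    assignments$actual <- actual
    confusion <- confusion_matrix_rhd(assignments$label, actual)
    accuracy <- mean(assignments$label == actual)
  }
  list(assignments = assignments, m1 = m1, m2 = m2,
       confusion = confusion, accuracy = accuracy)
}
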