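#' Cross-validation / ensemble configuration
#'
#' Each algorithm is run under `n_folds`-fold cross-validation repeated
#' `n_repeats` times; every held-out item receives one vote per
#' (algorithm, repeat), so tallies sum to
#' `length(algorithms) * n_repeats` (160 at the defaults). At image
#' level, folds are grouped by sample by default so no fold mixes images
#' of one sample between training and testing.
#'
#' @param n_folds folds per repeat (default 5).
#' @param n_repeats repeats (default 40).
#' @param algorithms subset of `c("RF", "SVM", "KNN", "GP")`.
#' @param seed stream seed for the fold draws and stochastic learners.
#' @param group_by_sample group image-level folds by sample.
#' @param rf_ntree,rf_maxdepth random-forest size.
#' @param svm_C SVM box constraint.
#' @param knn_k neighbours for kNN.
#' @param gp [gp_config()] for the GP learner.
#' @param feature_transform `"log1p"` (default) applies `log1p` to the
#'   non-negative feature columns before z-scoring: peak counts and
#'   densities span two orders of magnitude between D+ and D-, and on
#'   the raw scale the low-expression classes collapse into a sliver of
#'   the z-scored range; `"none"` uses the raw features.
#' @param max_fold_retries redraws allowed when a training fold misses a
#'   class.
#' @return object of class `rhd_cv_config`.
#' @export
cv_config <- function(n_folds = 5, n_repeats = 40,
                      algorithms = c("RF", "SVM", "KNN", "GP"),
                      seed = 1L, group_by_sample = TRUE,
                      rf_ntree = 100, rf_maxdepth = 25,
                      svm_C = 1, knn_k = 5, gp = gp_config(),
                      feature_transform = c("log1p", "none"),
                      max_fold_retries = 20) {
  stopifnot(n_folds >= 2, n_repeats >= 1, length(algorithms) >= 1,
            all(algorithms %in% c("RF", "SVM", "KNN", "GP")))
  feature_transform <- match.arg(feature_transform)
  structure(as.list(environment()), class = "rhd_cv_config")
}

# stratified group-fold assignment: per class round-robin with a random
# offset; redraws until every training set covers every class
draw_folds <- function(group_ids, group_labels, n_folds, max_retries) {
  classes <- unique(group_labels)
  for (try in seq_len(max_retries)) {
    fold <- integer(length(group_ids))
    for (cl in classes) {
      idx <- which(group_labels == cl)
      idx <- idx[sample.int(length(idx))]
      off <- sample.int(n_folds, 1)
      fold[idx] <- ((seq_along(idx) + off) %% n_folds) + 1
    }
    ok <- all(vapply(seq_len(n_folds), function(f)
      all(classes %in% group_labels[fold != f]), logical(1)))
    if (ok) return(fold)
  }
  stop("could not draw stratified folds with every class in every ",
       "training set after ", max_retries, " attempts")
}

#' Accumulate cross-validated ensemble votes
#'
#' For each algorithm and repeat a fresh (seeded) fold partition is
#' drawn; models are trained on the training folds (features z-scored
#' with training-fold statistics only) and each held-out item receives
#' exactly one vote, so every item's tally sums to
#' `length(algorithms) * n_repeats`.
#'
#' @param table data.frame with columns `item_id`, `sample_id`, `label`
#'   and the feature columns.
#' @param level `"image"` (items grouped by `sample_id` when configured)
#'   or `"sample"`.
#' @param cfg [cv_config()].
#' @param feature_cols feature column names (default the seven
#'   classification features).
#' @return integer matrix items x classes of votes, with `item_id` row
#'   names and attribute `classes`.
#' @export
train_vote <- function(table, level = c("image", "sample"), cfg = cv_config(),
                       feature_cols = feature_names()) {
  level <- match.arg(level)
  stopifnot(all(c("item_id", "sample_id", "label", feature_cols) %in% names(table)),
            !anyDuplicated(table$item_id))
  classes <- if (all(table$label %in% rhd_labels()))
    intersect(rhd_labels(), unique(table$label)) else sort(unique(table$label))
  if (length(classes) < 2) stop("need at least two classes to train")
  K <- length(classes)
  y <- match(table$label, classes)
  prio <- match(vote_priority(classes), classes)
  X <- as.matrix(table[, feature_cols])
  if (identical(cfg$feature_transform, "log1p")) {
    nonneg <- apply(X, 2, function(v) all(v >= 0))
    X[, nonneg] <- log1p(X[, nonneg])
  }
  grouped <- level == "image" && isTRUE(cfg$group_by_sample)
  group_of_item <- if (grouped) table$sample_id else table$item_id
  groups <- unique(group_of_item)
  if (length(groups) < cfg$n_folds)
    stop("fewer groups (", length(groups), ") than folds (", cfg$n_folds, ")")
  group_labels <- table$label[match(groups, group_of_item)]
  if (grouped && any(tapply(table$label, table$sample_id,
                            function(l) length(unique(l))) > 1))
    stop("images of one sample carry different labels")
  votes <- matrix(0L, nrow(table), K,
                  dimnames = list(table$item_id, classes))
  for (alg in cfg$algorithms) {
    for (rep in seq_len(cfg$n_repeats)) {
      set.seed(derive_seed(cfg$seed, paste(level, alg, rep, sep = "/")))
      fold_of_group <- draw_folds(groups, group_labels, cfg$n_folds,
                                  cfg$max_fold_retries)
      fold <- fold_of_group[match(group_of_item, groups)]
      for (f in seq_len(cfg$n_folds)) {
        tr <- which(fold != f); te <- which(fold == f)
        if (length(te) == 0) next
        zs <- zscore_fit(X[tr, , drop = FALSE])
        Xtr <- zscore_apply(X[tr, , drop = FALSE], zs)
        Xte <- zscore_apply(X[te, , drop = FALSE], zs)
        model <- fit_model(alg, Xtr, y[tr], K, cfg)
        pred <- predict_model(model, Xte, prio)
        votes[cbind(te, pred)] <- votes[cbind(te, pred)] + 1L
      }
    }
  }
  attr(votes, "classes") <- classes
  votes
}

#' Majority vote over a tally
#'
#' @param tally named numeric vector of votes per class.
#' @return the winning class label; ties are broken by
#'   [vote_priority()].
#' @export
majority_vote <- function(tally) {
  if (sum(tally) < 1) stop("empty vote tally")
  prio <- vote_priority(names(tally))
  winners <- names(tally)[tally == max(tally)]
  prio[prio %in% winners][1]
}

method_result <- function(sample_ids, tallies, n_items) {
  labels <- apply(tallies, 1, function(t) majority_vote(t))
  out <- data.frame(sample_id = sample_ids, label = labels,
                    n_items = n_items, row.names = NULL,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(tallies, row.names = NULL))
}

#' Method 1: image-level classification with per-sample vote pooling
#'
#' Every image is classified by the cross-validated ensemble; a sample's
#' tally is the element-wise sum of its images' tallies and its label
#' the majority class.
#'
#' @param image_table image-level feature table (`item_id`, `sample_id`,
#'   `label`, features).
#' @param cfg [cv_config()].
#' @return data.frame: `sample_id`, `label`, `n_items` (image count) and
#'   one vote column per class.
#' @export
classify_method1 <- function(image_table, cfg = cv_config()) {
  votes <- train_vote(image_table, "image", cfg)
  samples <- unique(image_table$sample_id)
  tallies <- t(vapply(samples, function(s)
    colSums(votes[image_table$sample_id == s, , drop = FALSE]),
    numeric(ncol(votes))))
  n_items <- vapply(samples, function(s) sum(image_table$sample_id == s),
                    numeric(1))
  method_result(samples, tallies, as.integer(n_items))
}

#' Method 2: sample-level classification on feature averages
#'
#' @param sample_table one row per sample (`item_id` = `sample_id`).
#' @param cfg [cv_config()].
#' @return data.frame as in [classify_method1()] with `n_items = 1`.
#' @export
classify_method2 <- function(sample_table, cfg = cv_config()) {
  votes <- train_vote(sample_table, "sample", cfg)
  method_result(sample_table$sample_id, votes, 1L)
}
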