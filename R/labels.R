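#' Rhesus D phenotype labels
#'
#' The four phenotype classes handled by the workflow, ordered by
#' decreasing D-antigen expression: `D_POS` (high), `WEAK_D` (reduced),
#' `DEL` (very low), `D_NEG` (absent).
#'
#' @return character vector of the four class labels.
#' @seealso [vote_priority()] for the tie-breaking order used in voting.
#' @export
rhd_labels <- function() c("D_POS", "WEAK_D", "DEL", "D_NEG")

#' Antibody channels
#'
#' The three monoclonal anti-D antibodies used for labelling; they bind
#' epitopes 3.1 (H41), 6.2 (BRAD3) and 9.1 (BIRMA-D6).
#'
#' @return character vector of channel names.
#' @export
antibody_channels <- function() c("H41", "BRAD3", "BIRMA_D6")

#' Tie-breaking priority for majority voting
#'
#' When classes tie for the vote maximum, the winner is the earliest
#' class in this priority order. For the RhD label set the order is
#' `DEL > WEAK_D > D_NEG > D_POS`: preferring the low-expression variants
#' flags potentially immunogenic donors for confirmatory testing rather
#' than silently passing them as D+ or D-. For any other label set the
#' order is the factor-level order of the supplied classes.
#'
#' @param classes character vector of class labels in tally order.
#' @return `classes` reordered from highest to lowest priority.
#' @export
vote_priority <- function(classes) {
  rhd_order <- c("DEL", "WEAK_D", "D_NEG", "D_POS")
  if (all(classes %in% rhd_order)) intersect(rhd_order, classes) else classes
}

assert_rhd_label <- function(x) {
  if (!all(x %in% rhd_labels()))
    stop("unknown RhD label: ", paste(setdiff(x, rhd_labels()), collapse = ", "))
  invisible(x)
}

assert_channel <- function(x) {
  if (!all(x %in% antibody_channels()))
    stop("unknown antibody channel: ", paste(setdiff(x, antibody_channels()), collapse = ", "))
  invisible(x)
}
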