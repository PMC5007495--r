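#' Binned peak-intensity histogram
#'
#' Half-open bins `[origin + i w, origin + (i+1) w)` with a shared
#' origin (default 0 counts) so histograms of different populations are
#' comparable bin by bin. Frequencies are normalised to sum to 1.
#'
#' @param intensities numeric vector of peak intensities (counts).
#' @param bin_width bin size in counts (default 50).
#' @param origin left edge of bin 0.
#' @return object of class `rhd_histogram`: `bin_width`, `origin`,
#'   `frequencies` (named by bin index), `n`.
#' @export
intensity_histogram <- function(intensities, bin_width = 50, origin = 0) {
  if (length(intensities) == 0) stop("empty intensity vector")
  stopifnot(bin_width > 0, all(intensities >= origin))
  bins <- floor((intensities - origin) / bin_width)
  tab <- table(bins)
  structure(list(bin_width = bin_width, origin = origin,
                 frequencies = as.numeric(tab) / length(intensities),
                 bin_index = as.integer(names(tab)),
                 n = length(intensities)),
            class = "rhd_histogram")
}

#' Overlap of two binned distributions
#'
#' The sum over the union of bins of the minimum of the two normalised
#' frequencies: symmetric, in `[0, 1]`, 1 for identical histograms, 0
#' for disjoint supports.
#'
#' @param h1,h2 [intensity_histogram()] objects with identical
#'   `bin_width` and `origin`.
#' @return overlap fraction in `[0, 1]`.
#' @export
distribution_overlap <- function(h1, h2) {
  stopifnot(inherits(h1, "rhd_histogram"), inherits(h2, "rhd_histogram"))
  if (h1$bin_width != h2$bin_width || h1$origin != h2$origin)
    stop("histograms have mismatched binning (width ", h1$bin_width, "/",
         h2$bin_width, ", origin ", h1$origin, "/", h2$origin, ")")
  bins <- union(h1$bin_index, h2$bin_index)
  f1 <- f2 <- numeric(length(bins))
  f1[match(h1$bin_index, bins)] <- h1$frequencies
  f2[match(h2$bin_index, bins)] <- h2$frequencies
  sum(pmin(f1, f2))
}

#' Pairwise distribution-overlap matrix over populations
#'
#' @param populations named list mapping class label to a numeric vector
#'   of peak intensities (at least two classes).
#' @param bin_width,origin binning shared by all histograms.
#' @return symmetric matrix with unit diagonal, one row/column per
#'   class.
#' @export
pairwise_overlap_matrix <- function(populations, bin_width = 50, origin = 0) {
  if (length(populations) < 2) stop("need at least two populations")
  hs <- lapply(populations, intensity_histogram, bin_width = bin_width,
               origin = origin)
  k <- length(hs)
  m <- diag(1, k)
  dimnames(m) <- list(names(populations), names(populations))
  for (a in seq_len(k - 1))
    for (b in (a + 1):k)
      m[a, b] <- m[b, a] <- distribution_overlap(hs[[a]], hs[[b]])
  m
}
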