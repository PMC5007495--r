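# Minimal baseline TIFF support: uncompressed, little-endian, 16-bit
# unsigned grayscale, one strip per page. This is the exact shape the
# simulator writes; the reader validates and refuses anything else.

tiff_tag <- function(id, type, count, value) {
  # returns the 12 raw bytes of one IFD entry; value must fit inline
  con <- raw(0)
  w2 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
  val <- if (type == 3) c(w2(value), as.raw(c(0, 0))) else w4(value)
  c(w2(id), w2(type), w4(count), val)
}

#' Write frames as a multi-page 16-bit TIFF
#'
#' @param frames list of numeric matrices (values clamped to
#'   `[0, 65535]` and rounded).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tiff16 <- function(frames, path) {
  stopifnot(length(frames) >= 1, all(vapply(frames, is.matrix, logical(1))))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(as.integer(42), con, size = 2, endian = "little")
  n <- length(frames)
  sizes <- vapply(frames, function(f) 2L * length(f), integer(1))
  data_off <- 8L + c(0L, cumsum(sizes))[seq_len(n)]
  ifd_size <- 2L + 9L * 12L + 4L
  ifd_off <- 8L + sum(sizes) + (seq_len(n) - 1L) * ifd_size
  writeBin(as.integer(ifd_off[1]), con, size = 4, endian = "little")
  for (f in frames) {
    v <- as.integer(round(pmin(pmax(t(f), 0), 65535)))   # row-major
    v[v > 32767L] <- v[v > 32767L] - 65536L              # low 16 bits
    writeBin(as.vector(v), con, size = 2, endian = "little")
  }
  for (k in seq_len(n)) {
    H <- nrow(frames[[k]]); W <- ncol(frames[[k]])
    writeBin(as.integer(9), con, size = 2, endian = "little")
    entries <- c(
      tiff_tag(256, 4, 1, W),            # ImageWidth
      tiff_tag(257, 4, 1, H),            # ImageLength
      tiff_tag(258, 3, 1, 16),           # BitsPerSample
      tiff_tag(259, 3, 1, 1),            # Compression: none
      tiff_tag(262, 3, 1, 1),            # Photometric: BlackIsZero
      tiff_tag(273, 4, 1, data_off[k]),  # StripOffsets
      tiff_tag(277, 3, 1, 1),            # SamplesPerPixel
      tiff_tag(278, 4, 1, H),            # RowsPerStrip
      tiff_tag(279, 4, 1, sizes[k]))     # StripByteCounts
    writeBin(entries, con)
    nxt <- if (k < n) ifd_off[k + 1] else 0L
    writeBin(as.integer(nxt), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a multi-page 16-bit TIFF written by [write_tiff16()]
#'
#' @param path file path.
#' @return list of numeric matrices.
#' @export
read_tiff16 <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  fail <- function(msg) stop("TIFF ", path, ": ", msg)
  if (length(raw) < 8) fail("truncated header")
  if (rawToChar(raw[1:2]) != "II") fail("not little-endian TIFF")
  u <- function(off, size) {
    if (off + size - 1 > length(raw)) fail("truncated file")
    sum(as.integer(raw[off:(off + size - 1)]) * 256^(0:(size - 1)))
  }
  if (u(3, 2) != 42) fail("bad magic")
  frames <- list()
  off <- u(5, 4)
  while (off != 0) {
    nent <- u(off + 1, 2)
    tags <- list()
    for (e in seq_len(nent)) {
      base <- off + 2 + (e - 1) * 12
      id <- u(base + 1, 2); type <- u(base + 3, 2)
      val <- if (type == 3) u(base + 9, 2) else u(base + 9, 4)
      tags[[as.character(id)]] <- val
    }
    need <- c("256", "257", "273", "279")
    if (!all(need %in% names(tags))) fail("missing required tags")
    if (!is.null(tags[["259"]]) && tags[["259"]] != 1) fail("compressed TIFF unsupported")
    if (!is.null(tags[["258"]]) && tags[["258"]] != 16) fail("only 16-bit supported")
    W <- tags[["256"]]; H <- tags[["257"]]
    so <- tags[["273"]]; bc <- tags[["279"]]
    if (bc != 2 * H * W) fail("strip size mismatch")
    if (so + bc - 1 > length(raw)) fail("truncated pixel data")
    v <- readBin(raw[(so + 1):(so + bc)], "integer", n = H * W, size = 2,
                 signed = FALSE, endian = "little")
    frames[[length(frames) + 1]] <- t(matrix(as.numeric(v), nrow = W, ncol = H))
    off <- u(off + 2 + nent * 12 + 1, 4)
  }
  if (length(frames) == 0) fail("no pages")
  frames
}

#' Write / read an image stack (TIFF + modality sidecar)
#'
#' The pixel data go to `<path>`; frame modality and pixel pitch go to a
#' JSON sidecar `<path>.meta.json`. Reading without the sidecar is an
#' explicit error naming the file, since frames cannot be interpreted
#' without their modality.
#'
#' @param stack an `rhd_stack` (see [simulate_image()]).
#' @param path TIFF file path.
#' @return `read_image_stack` returns an `rhd_stack`.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "rhd_stack"))
  write_tiff16(stack$frames, path)
  jsonlite::write_json(list(modality = stack$modality,
                            n_bf = sum(stack$modality == "BF"),
                            pixel_pitch_um = stack$pixel_pitch_um),
                       paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path) {
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(meta_path))
    stop("missing modality sidecar for image stack: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  frames <- read_tiff16(path)
  if (length(meta$modality) != length(frames))
    stop("sidecar ", meta_path, " lists ", length(meta$modality),
         " frames but TIFF has ", length(frames))
  structure(list(frames = frames, modality = meta$modality,
                 pixel_pitch_um = meta$pixel_pitch_um),
            class = "rhd_stack")
}
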