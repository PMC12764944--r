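# Minimal baseline TIFF reader/writer for grayscale scientific maps.
#
# Result maps (DoLD, AoLD, masks) are float-valued and may contain NaN; they
# must round-trip losslessly. This codec writes uncompressed single-sample
# float32 multi-page TIFF (little-endian, one strip per page) and reads the
# uncompressed grayscale subset (uint8/16/32 and float32/64, single- or
# multi-strip, either byte order), which covers its own output and plain
# exports from common scientific tools.

TIFF_TYPE_SIZE <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L, `6` = 1L,
                    `7` = 1L, `8` = 2L, `9` = 4L, `10` = 8L, `11` = 4L, `12` = 8L)

#' Write matrices as a multi-page float32 TIFF
#'
#' @param images A matrix or list of numeric matrices (pages). `NaN`/`Inf`
#'   are preserved at float32 precision.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tiff_float <- function(images, path) {
  if (is.matrix(images)) images <- list(images)
  stopifnot(length(images) >= 1, all(vapply(images, is.matrix, TRUE)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, 2, eos = NULL)
  writeBin(c(42L), con, size = 2, endian = "little")
  writeBin(8L, con, size = 4, endian = "little")  # first IFD right after header
  offset <- 8L
  n <- length(images)
  for (k in seq_len(n)) {
    m <- images[[k]]
    h <- nrow(m); w <- ncol(m)
    nbytes <- 4L * h * w
    ifd_offset <- offset        # IFD first, then pixel data
    n_entries <- 10L
    ifd_size <- 2L + n_entries * 12L + 4L
    data_offset <- ifd_offset + ifd_size
    entry <- function(tag, type, count, value) {
      writeBin(as.integer(tag), con, size = 2, endian = "little")
      writeBin(as.integer(type), con, size = 2, endian = "little")
      writeBin(as.integer(count), con, size = 4, endian = "little")
      if (type == 3) {  # SHORT: value left-justified in the 4-byte slot
        writeBin(as.integer(value), con, size = 2, endian = "little")
        writeBin(0L, con, size = 2, endian = "little")
      } else {
        writeBin(as.integer(value), con, size = 4, endian = "little")
      }
    }
    writeBin(n_entries, con, size = 2, endian = "little")
    entry(256, 4, 1, w)            # ImageWidth
    entry(257, 4, 1, h)            # ImageLength
    entry(258, 3, 1, 32)           # BitsPerSample
    entry(259, 3, 1, 1)            # Compression: none
    entry(262, 3, 1, 1)            # Photometric: BlackIsZero
    entry(273, 4, 1, data_offset)  # StripOffsets
    entry(277, 3, 1, 1)            # SamplesPerPixel
    entry(278, 4, 1, h)            # RowsPerStrip
    entry(279, 4, 1, nbytes)       # StripByteCounts
    entry(339, 3, 1, 3)            # SampleFormat: IEEE float
    next_ifd <- if (k < n) data_offset + nbytes else 0L
    writeBin(as.integer(next_ifd), con, size = 4, endian = "little")
    writeBin(as.numeric(t(m)), con, size = 4, endian = "little")  # row-major
    offset <- data_offset + nbytes
  }
  invisible(path)
}

#' Read a grayscale TIFF into a list of matrices
#'
#' Reads the uncompressed single-sample subset of baseline TIFF: unsigned
#' integer (8/16/32-bit) or IEEE float (32/64-bit) samples, any number of
#' strips, little- or big-endian.
#'
#' @param path TIFF file path.
#' @return List of numeric matrices, one per page.
#' @export
read_tiff_float <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 8) stop("not a TIFF file: ", path)
  endian <- if (raw[1] == as.raw(0x49)) "little" else if (raw[1] == as.raw(0x4d)) "big"
    else stop("not a TIFF file: ", path)
  u <- function(at, size) {
    # unsigned integer read at 0-based byte offset `at`
    if (size == 4) {  # readBin size=4 is signed; recover unsigned via double
      v <- readBin(raw[(at + 1):(at + 4)], "integer", 1, size = 4, endian = endian)
      if (v < 0) v + 2^32 else v
    } else {
      readBin(raw[(at + 1):(at + size)], "integer", 1, size = size,
              signed = FALSE, endian = endian)
    }
  }
  magic <- u(2, 2)
  if (magic != 42) stop("not a baseline TIFF (magic ", magic, ")")
  ifd <- u(4, 4)
  pages <- list()
  while (ifd != 0) {
    n_entries <- u(ifd, 2)
    tags <- list()
    for (i in seq_len(n_entries)) {
      at <- ifd + 2 + (i - 1) * 12
      tag <- u(at, 2); type <- u(at + 2, 2); count <- u(at + 4, 4)
      size <- unname(TIFF_TYPE_SIZE[as.character(type)])
      if (is.na(size)) next
      total <- size * count
      vat <- if (total <= 4) at + 8 else u(at + 8, 4)
      vals <- if (type %in% c(3, 4, 1)) {
        vapply(seq_len(count), function(j) u(vat + (j - 1) * size, size), 0)
      } else NULL
      tags[[as.character(tag)]] <- vals
    }
    g <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) default else v
    }
    w <- g(256); h <- g(257)
    if (is.null(w) || is.null(h)) stop("TIFF page missing dimensions")
    bits <- g(258, 1)[1]
    if (g(259, 1)[1] != 1) stop("compressed TIFF not supported")
    if (g(277, 1)[1] != 1) stop("only single-sample (grayscale) TIFF supported")
    fmt <- g(339, 1)[1]
    offsets <- g(273); counts <- g(279)
    if (is.null(offsets)) stop("TIFF page missing strip offsets")
    if (is.null(counts)) counts <- rep((bits / 8) * w * h / length(offsets), length(offsets))
    bytes <- unlist(lapply(seq_along(offsets), function(j)
      raw[(offsets[j] + 1):(offsets[j] + counts[j])]))
    npix <- w * h
    vals <- if (fmt == 3) {
      if (bits == 32) readBin(bytes, "numeric", npix, size = 4, endian = endian)
      else if (bits == 64) readBin(bytes, "numeric", npix, size = 8, endian = endian)
      else stop("unsupported float bit depth: ", bits)
    } else if (fmt %in% c(1, NA) || is.na(fmt)) {
      if (bits == 8) as.numeric(readBin(bytes, "integer", npix, size = 1,
                                        signed = FALSE, endian = endian))
      else if (bits == 16) as.numeric(readBin(bytes, "integer", npix, size = 2,
                                              signed = FALSE, endian = endian))
      else if (bits == 32) {
        v <- readBin(bytes, "integer", npix, size = 4, endian = endian)
        ifelse(v < 0, v + 2^32, as.numeric(v))
      } else stop("unsupported integer bit depth: ", bits)
    } else stop("unsupported TIFF sample format: ", fmt)
    pages[[length(pages) + 1]] <- matrix(vals, h, w, byrow = TRUE)
    ifd <- u(ifd + 2 + n_entries * 12, 4)
  }
  pages
}
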