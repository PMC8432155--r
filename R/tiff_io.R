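#' Write a multi-page 16-bit grayscale TIFF
#'
#' Minimal baseline TIFF writer (uncompressed, little-endian, one strip per
#' page). One page is written per channel, which is how multi-channel fields
#' and labeled masks are stored on disk. No R TIFF bindings are assumed to be
#' present, so the byte layout is produced directly.
#'
#' @param channels a list of integer/numeric matrices with equal dimensions;
#'   values must lie in \[0, 65535\] and are rounded to integers.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_tiff16()]
#' @export
write_tiff16 <- function(channels, path) {
  if (is.matrix(channels)) channels <- list(channels)
  stopifnot(length(channels) >= 1)
  dims <- lapply(channels, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1)
    stop("all channels must share the same shape")
  nr <- nrow(channels[[1]]); nc <- ncol(channels[[1]])
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)                       # little-endian
  writeBin(as.integer(42), con, size = 2, endian = "little")
  # layout: [8-byte header][page1 pixels][page1 IFD][page2 pixels][IFD]...
  offset <- 8L
  n_pages <- length(channels)
  ifd_entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3) {                                   # SHORT, left-justified
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  writeBin(as.integer(offset + 0L), con, size = 4, endian = "little")  # placeholder rewritten below
  # first IFD pointer: pixels come first, so IFD sits after the pixel strip
  strip_bytes <- nr * nc * 2L
  seek(con, 4)
  writeBin(as.integer(8L + strip_bytes), con, size = 4, endian = "little")
  pos <- 8L
  for (p in seq_len(n_pages)) {
    seek(con, pos)
    m <- channels[[p]]
    v <- as.integer(round(t(m)))                       # row-major pixel order
    if (any(v < 0 | v > 65535)) stop("pixel values outside [0, 65535]")
    writeBin(v, con, size = 2, endian = "little")
    strip_off <- pos
    ifd_off <- pos + strip_bytes
    seek(con, ifd_off)
    n_entries <- 8L
    writeBin(n_entries, con, size = 2, endian = "little")
    ifd_entry(256, 3, 1, nc)                           # ImageWidth
    ifd_entry(257, 3, 1, nr)                           # ImageLength
    ifd_entry(258, 3, 1, 16)                           # BitsPerSample
    ifd_entry(259, 3, 1, 1)                            # Compression: none
    ifd_entry(262, 3, 1, 1)                            # Photometric: BlackIsZero
    ifd_entry(273, 4, 1, strip_off)                    # StripOffsets
    ifd_entry(278, 3, 1, nr)                           # RowsPerStrip
    ifd_entry(279, 4, 1, strip_bytes)                  # StripByteCounts
    after_ifd <- ifd_off + 2L + n_entries * 12L + 4L
    # next page: pixels at after_ifd, its IFD after that pixel strip
    next_ifd <- if (p < n_pages) after_ifd + strip_bytes else 0L
    writeBin(as.integer(next_ifd), con, size = 4, endian = "little")
    pos <- after_ifd
  }
  invisible(path)
}

#' Read a multi-page 16-bit grayscale TIFF
#'
#' Companion reader for [write_tiff16()]. Supports uncompressed little-endian
#' baseline TIFF with 16-bit grayscale pages (possibly multi-strip).
#'
#' @param path file path.
#' @return a list of integer matrices, one per page.
#' @export
read_tiff16 <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (!identical(rawToChar(raw[1:2]), "II"))
    stop("only little-endian TIFF is supported")
  u16 <- function(i) as.integer(raw[i]) + 256L * as.integer(raw[i + 1])
  u32 <- function(i) as.integer(raw[i]) + 256 * as.integer(raw[i + 1]) +
    65536 * as.integer(raw[i + 2]) + 16777216 * as.integer(raw[i + 3])
  stopifnot(u16(3) == 42)
  ifd <- u32(5)
  pages <- list()
  while (ifd != 0) {
    n <- u16(ifd + 1)
    tags <- list()
    for (e in seq_len(n)) {
      base <- ifd + 2 + (e - 1) * 12
      tag <- u16(base + 1); type <- u16(base + 3); count <- u32(base + 5)
      val <- if (type == 3) u16(base + 9) else u32(base + 9)
      # multi-valued LONG/SHORT entries store an offset instead
      if ((type == 3 && count > 2) || (type == 4 && count > 1)) {
        off <- u32(base + 9)
        val <- if (type == 3)
          vapply(seq_len(count), function(k) u16(off + 1 + (k - 1) * 2), 0L)
        else
          vapply(seq_len(count), function(k) u32(off + 1 + (k - 1) * 4), 0)
      }
      tags[[as.character(tag)]] <- val
    }
    w <- tags[["256"]]; h <- tags[["257"]]
    if (!is.null(tags[["259"]]) && tags[["259"]] != 1)
      stop("compressed TIFF not supported")
    offs <- tags[["273"]]; cnts <- tags[["279"]]
    vals <- integer(0)
    for (s in seq_along(offs)) {
      seg <- raw[(offs[s] + 1):(offs[s] + cnts[s])]
      lo <- as.integer(seg[seq(1, length(seg), 2)])
      hi <- as.integer(seg[seq(2, length(seg), 2)])
      vals <- c(vals, lo + 256L * hi)
    }
    pages[[length(pages) + 1]] <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
    ifd <- u32(ifd + 2 + n * 12 + 1)
  }
  pages
}
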