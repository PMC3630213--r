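# Minimal multi-page grayscale TIFF codec (uncompressed, 8/16-bit).
# No TIFF reader exists in this R installation, so the subset of the format
# the package needs is implemented here: baseline TIFF, PhotometricInterpretation
# 0/1, Compression 1, one sample per pixel, strip-organized, II or MM byte order.

TIFF_TAGS <- c(
  ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
  Compression = 259L, Photometric = 262L, StripOffsets = 273L,
  RowsPerStrip = 278L, StripByteCounts = 279L
)

#' Read a multi-page grayscale TIFF into a list of integer matrices
#'
#' Supports the uncompressed baseline subset this package writes: 8- or
#' 16-bit, single channel, any strip layout, little- or big-endian.
#'
#' @param path file path.
#' @return list with `pages` (list of integer matrices, row = image row) and
#'   `bits` (8 or 16).
#' @keywords internal
read_tiff_gray <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8) stop("not a TIFF file: ", path)
  order <- rawToChar(raw[1:2])
  endian <- switch(order, II = "little", MM = "big",
                   stop("not a TIFF file (bad byte order mark): ", path))
  u16 <- function(off) readBin(raw[(off + 1):(off + 2)], "integer",
                               size = 2, signed = FALSE, endian = endian)
  u32 <- function(off) {
    v <- readBin(raw[(off + 1):(off + 4)], "integer", size = 4, endian = endian)
    if (v < 0) v <- v + 2^32
    v
  }
  if (u16(2) != 42L) stop("not a TIFF file (bad magic): ", path)

  read_entry_values <- function(off) {
    typ <- u16(off + 2); cnt <- u32(off + 4)
    size <- c(1L, 1L, 2L, 4L)[typ]  # BYTE, ASCII, SHORT, LONG
    if (is.na(size)) return(NULL)
    total <- size * cnt
    voff <- if (total <= 4) off + 8 else u32(off + 8)
    vapply(seq_len(cnt) - 1L, function(i) {
      if (size == 2L) u16(voff + 2 * i)
      else if (size == 4L) u32(voff + 4 * i)
      else as.integer(raw[voff + i + 1])
    }, numeric(1))
  }

  pages <- list(); bits_seen <- NULL
  ifd <- u32(4)
  while (ifd != 0) {
    n <- u16(ifd)
    tags <- list()
    for (k in seq_len(n)) {
      off <- ifd + 2 + 12 * (k - 1)
      tag <- u16(off)
      nm <- names(TIFF_TAGS)[match(tag, TIFF_TAGS)]
      if (!is.na(nm)) tags[[nm]] <- read_entry_values(off)
    }
    W <- as.integer(tags$ImageWidth); H <- as.integer(tags$ImageLength)
    bits <- if (is.null(tags$BitsPerSample)) 8L else as.integer(tags$BitsPerSample[1])
    comp <- if (is.null(tags$Compression)) 1L else as.integer(tags$Compression[1])
    if (comp != 1L) stop("unsupported TIFF compression (only uncompressed supported)")
    if (!bits %in% c(8L, 16L)) stop("unsupported TIFF bit depth: ", bits)
    bytes <- integer(0)
    dat <- raw(0)
    for (s in seq_along(tags$StripOffsets)) {
      so <- tags$StripOffsets[s]; sc <- tags$StripByteCounts[s]
      dat <- c(dat, raw[(so + 1):(so + sc)])
    }
    px <- if (bits == 8L) {
      as.integer(dat)
    } else {
      readBin(dat, "integer", n = length(dat) / 2, size = 2,
              signed = FALSE, endian = endian)
    }
    if (length(px) != W * H) stop("TIFF strip data does not match dimensions")
    pages[[length(pages) + 1L]] <- matrix(px, nrow = H, ncol = W, byrow = TRUE)
    bits_seen <- c(bits_seen, bits)
    ifd <- u32(ifd + 2 + 12 * n)
  }
  if (!length(pages)) stop("TIFF file contains no images: ", path)
  list(pages = pages, bits = bits_seen[1])
}

#' Write integer matrices as a multi-page grayscale TIFF
#'
#' @param pages list of integer matrices (all same dimensions), values in
#'   `[0, 2^bits - 1]`.
#' @param path output path.
#' @param bits 8 or 16.
#' @keywords internal
write_tiff_gray <- function(pages, path, bits = 16L) {
  if (is.matrix(pages)) pages <- list(pages)
  bits <- as.integer(bits)
  stopifnot(bits %in% c(8L, 16L))
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  u16r <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
  u32r <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
  entry <- function(tag, type, count, value) {
    val <- if (type == 3L) c(u16r(value), u16r(0L)) else u32r(value)
    c(u16r(tag), u16r(type), u32r(count), val)
  }
  bytes_per_px <- bits / 8L
  strip_size <- H * W * bytes_per_px
  n_entries <- 8L
  ifd_size <- 2 + 12 * n_entries + 4
  out <- c(charToRaw("II"), u16r(42L), u32r(8L + strip_size))
  offset <- 8L
  for (p in seq_along(pages)) {
    m <- pages[[p]]
    if (nrow(m) != H || ncol(m) != W) stop("all TIFF pages must share dimensions")
    data_off <- offset
    px <- as.integer(t(m))
    if (any(px < 0L | px > 2^bits - 1L)) stop("pixel values out of range for ", bits, "-bit TIFF")
    dat <- if (bits == 8L) as.raw(px) else writeBin(px, raw(), size = 2, endian = "little")
    ifd_off <- data_off + strip_size
    next_off <- if (p < length(pages)) ifd_off + ifd_size + strip_size else 0L
    ifd <- c(
      u16r(n_entries),
      entry(256L, 3L, 1L, W),
      entry(257L, 3L, 1L, H),
      entry(258L, 3L, 1L, bits),
      entry(259L, 3L, 1L, 1L),   # no compression
      entry(262L, 3L, 1L, 1L),   # BlackIsZero
      entry(273L, 4L, 1L, data_off),
      entry(278L, 3L, 1L, H),
      entry(279L, 4L, 1L, strip_size),
      u32r(next_off)
    )
    out <- c(out, dat, ifd)
    offset <- ifd_off + ifd_size
  }
  writeBin(out, path)
  invisible(path)
}
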