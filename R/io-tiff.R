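# Minimal multi-page TIFF codec (uncompressed, little endian, grayscale
# float32).  One page per channel; enough for fluorescence phantom I/O
# without an external TIFF library.

#' Write matrices as a multi-page grayscale TIFF
#'
#' Each element of `pages` (a matrix, or a named list of matrices of one
#' shape) becomes one 32-bit float page.  Channel order is preserved; page
#' names are not stored in the file, so keep the channel declaration in
#' config (as the CLI does).
#'
#' @param pages matrix or list of matrices (rows = image height).
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(pages, path) {
  if (is.matrix(pages)) pages <- list(pages)
  if (!length(pages)) stop_bscb("no pages to write")
  dims <- unique(lapply(pages, dim))
  if (length(dims) != 1L) stop_bscb("all TIFF pages must share one shape")
  h <- dims[[1]][1]; w <- dims[[1]][2]

  con <- file(path, "wb")
  on.exit(close(con))
  wI <- function(v, size) writeBin(as.integer(v), con, size = size, endian = "little")

  n <- length(pages)
  strip_bytes <- h * w * 4L
  # layout: 8-byte header | page data blocks | IFD chain
  data_off <- 8L + (seq_len(n) - 1L) * strip_bytes
  ifd_bytes <- 2L + 10L * 12L + 4L
  ifd_off <- 8L + n * strip_bytes + (seq_len(n) - 1L) * ifd_bytes

  writeBin(charToRaw("II"), con); wI(42L, 2); wI(ifd_off[1], 4)
  for (p in pages) {
    # TIFF rows are stored top-to-bottom, row-major
    writeBin(as.numeric(t(p)), con, size = 4L, endian = "little")
  }
  tag <- function(id, type, count, value) {
    wI(id, 2); wI(type, 2); wI(count, 4)
    if (type == 3L) { wI(value, 2); wI(0L, 2) } else wI(value, 4)
  }
  for (i in seq_len(n)) {
    wI(10L, 2)
    tag(256L, 4L, 1L, w)               # ImageWidth
    tag(257L, 4L, 1L, h)               # ImageLength
    tag(258L, 3L, 1L, 32L)             # BitsPerSample
    tag(259L, 3L, 1L, 1L)              # Compression: none
    tag(262L, 3L, 1L, 1L)              # Photometric: BlackIsZero
    tag(273L, 4L, 1L, data_off[i])     # StripOffsets
    tag(277L, 3L, 1L, 1L)              # SamplesPerPixel
    tag(278L, 4L, 1L, h)               # RowsPerStrip
    tag(279L, 4L, 1L, strip_bytes)     # StripByteCounts
    tag(339L, 3L, 1L, 3L)              # SampleFormat: IEEE float
    wI(if (i < n) ifd_off[i + 1] else 0L, 4)
  }
  invisible(path)
}

#' Read a multi-page grayscale TIFF written by [write_tiff()]
#'
#' Supports uncompressed little-endian single-sample pages (8/16-bit
#' unsigned integer or 32-bit float), with any strip layout.
#'
#' @param path `.tif` file path.
#' @return list of numeric matrices, one per page.
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  rI <- function(off, size, n = 1L, signed = TRUE)
    readBin(raw[(off + 1):(off + size * n)], "integer", n = n, size = size,
            signed = signed, endian = "little")
  if (rawToChar(raw[1:2]) != "II") stop_bscb("only little-endian TIFF supported")
  if (rI(2, 2) != 42L) stop_bscb("not a TIFF file: %s", path)

  pages <- list()
  ifd <- rI(4, 4)
  while (ifd != 0L) {
    ntag <- rI(ifd, 2)
    tags <- list()
    for (k in seq_len(ntag)) {
      base <- ifd + 2L + (k - 1L) * 12L
      id <- rI(base, 2, signed = FALSE)
      type <- rI(base + 2, 2)
      count <- rI(base + 4, 4)
      val_off <- base + 8L
      rd_vals <- function(off, type, count) {
        if (type == 3L) rI(off, 2, count, signed = FALSE)
        else rI(off, 4, count)
      }
      inline_bytes <- count * (if (type == 3L) 2L else 4L)
      vals <- if (inline_bytes <= 4L) rd_vals(val_off, type, count)
              else rd_vals(rI(val_off, 4), type, count)
      tags[[as.character(id)]] <- vals
    }
    g <- function(id, default = NULL) {
      v <- tags[[as.character(id)]]
      if (is.null(v)) default else v
    }
    w <- g(256); h <- g(257)
    bits <- g(258, 1L)[1]
    if (g(259, 1L) != 1L) stop_bscb("compressed TIFF not supported")
    fmt <- g(339, 1L)[1]
    offsets <- g(273); counts <- g(279, h * w * bits / 8)
    buf <- raw(0)
    for (s in seq_along(offsets))
      buf <- c(buf, raw[(offsets[s] + 1):(offsets[s] + counts[s])])
    npix <- h * w
    vals <- if (fmt == 3L && bits == 32L) {
      readBin(buf, "double", n = npix, size = 4L, endian = "little")
    } else if (fmt <= 1L && bits == 8L) {
      as.numeric(readBin(buf, "integer", n = npix, size = 1L, signed = FALSE))
    } else if (fmt <= 1L && bits == 16L) {
      as.numeric(readBin(buf, "integer", n = npix, size = 2L, signed = FALSE,
                         endian = "little"))
    } else stop_bscb("unsupported TIFF sample format (fmt=%d bits=%d)", fmt, bits)
    pages[[length(pages) + 1L]] <- t(matrix(vals, nrow = w, ncol = h))
    ifd <- rI(ifd + 2L + ntag * 12L, 4)
  }
  pages
}
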