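# Minimal baseline TIFF codec (little-endian, uncompressed, grayscale,
# 8/16-bit, one strip per page). No R TIFF binding is available in the target
# environment, so the subset of TIFF 6.0 needed for speckle movies is
# implemented here. High-speed camera stacks are plain uncompressed grayscale
# pages, which is exactly this subset.

.TIFF_TAGS <- c(ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
                Compression = 259L, Photometric = 262L, StripOffsets = 273L,
                SamplesPerPixel = 277L, RowsPerStrip = 278L,
                StripByteCounts = 279L, SampleFormat = 339L)

# frames: integer array h x w x n. storage_bits: 8 or 16.
write_tiff_stack <- function(frames, path, storage_bits = 16L) {
  d <- dim(frames)
  if (length(d) != 3L) stop_sr("frames must be a h x w x n_frames array")
  h <- d[1L]; w <- d[2L]; n <- d[3L]
  if (!storage_bits %in% c(8L, 16L)) stop_sr("storage_bits must be 8 or 16")
  bpp <- storage_bits %/% 8L
  strip_bytes <- h * w * bpp
  n_tags <- 10L
  ifd_size <- 2L + n_tags * 12L + 4L
  con <- file(path, "wb")
  on.exit(close(con))
  wr2 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  wr4 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  # header
  writeBin(charToRaw("II"), con); wr2(42L); wr4(8L)
  # layout: header(8) | [IFD_i | pixel data_i] ...
  off <- 8L
  for (i in seq_len(n)) {
    data_off <- off + ifd_size
    next_ifd <- if (i < n) data_off + strip_bytes else 0L
    wr2(n_tags)
    tag <- function(id, type, count, value) { wr2(id); wr2(type); wr4(count);
      if (type == 3L) { wr2(value); wr2(0L) } else wr4(value) }
    tag(.TIFF_TAGS[["ImageWidth"]], 4L, 1L, w)
    tag(.TIFF_TAGS[["ImageLength"]], 4L, 1L, h)
    tag(.TIFF_TAGS[["BitsPerSample"]], 3L, 1L, storage_bits)
    tag(.TIFF_TAGS[["Compression"]], 3L, 1L, 1L)
    tag(.TIFF_TAGS[["Photometric"]], 3L, 1L, 1L)   # BlackIsZero
    tag(.TIFF_TAGS[["StripOffsets"]], 4L, 1L, data_off)
    tag(.TIFF_TAGS[["SamplesPerPixel"]], 3L, 1L, 1L)
    tag(.TIFF_TAGS[["RowsPerStrip"]], 4L, 1L, h)
    tag(.TIFF_TAGS[["StripByteCounts"]], 4L, 1L, strip_bytes)
    tag(.TIFF_TAGS[["SampleFormat"]], 3L, 1L, 1L)  # unsigned integer
    wr4(next_ifd)
    # pixel data, row-major (TIFF scanline order)
    page <- t(frames[, , i])                        # column-major -> row-major
    writeBin(as.integer(page), con, size = bpp, endian = "little")
    off <- data_off + strip_bytes
  }
  invisible(path)
}

read_tiff_stack <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8L) stop_sr("not a TIFF file: ", path)
  if (rawToChar(raw[1:2]) != "II")
    stop_sr("only little-endian TIFF is supported")
  rd <- function(at, size) {
    b <- as.integer(raw[at:(at + size - 1L)])
    sum(b * 256^(seq_len(size) - 1L))
  }
  if (rd(3L, 2L) != 42L) stop_sr("not a TIFF file: ", path)
  ifd <- rd(5L, 4L)
  pages <- list()
  while (ifd != 0L) {
    n_tags <- rd(ifd + 1L, 2L)
    tags <- list()
    for (j in seq_len(n_tags)) {
      e <- ifd + 2L + (j - 1L) * 12L + 1L
      id <- rd(e, 2L); type <- rd(e + 2L, 2L)
      val <- if (type == 3L) rd(e + 8L, 2L) else rd(e + 8L, 4L)
      tags[[as.character(id)]] <- val
    }
    g <- function(id, default = NULL) {
      v <- tags[[as.character(id)]]
      if (is.null(v)) { if (is.null(default)) stop_sr("TIFF tag ", id, " missing"); default } else v
    }
    if (g(259L, 1L) != 1L) stop_sr("compressed TIFF is not supported")
    w <- g(256L); h <- g(257L); bits <- g(258L, 8L)
    if (!bits %in% c(8L, 16L)) stop_sr("only 8/16-bit grayscale TIFF supported")
    off <- g(273L); nbytes <- g(279L, h * w * bits %/% 8L)
    bpp <- bits %/% 8L
    if (nbytes != h * w * bpp) stop_sr("unexpected strip size in TIFF")
    vals <- readBin(raw[(off + 1L):(off + nbytes)], "integer", n = h * w,
                    size = bpp, signed = FALSE, endian = "little")
    pages[[length(pages) + 1L]] <- t(matrix(vals, nrow = w, ncol = h))
    ifd <- rd(ifd + 2L + n_tags * 12L + 1L, 4L)
  }
  if (!length(pages)) stop_sr("TIFF contains no pages")
  h <- nrow(pages[[1L]]); w <- ncol(pages[[1L]])
  arr <- array(0L, dim = c(h, w, length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]]
  storage.mode(arr) <- "integer"
  arr
}
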