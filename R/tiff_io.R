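# Minimal multi-page 32-bit float TIFF writer (classic little-endian TIFF,
# one strip per page). Needed because the installed TIFF bindings only write
# integer sample formats; reading goes through libtiff (tiff::readTIFF),
# which handles IEEE-float pages natively.

write_float_tiff <- function(pages, path) {
  stopifnot(is.list(pages), length(pages) >= 1L,
            all(vapply(pages, is.matrix, logical(1))))
  con <- file(path, "wb")
  on.exit(close(con))
  w <- function(x, size) writeBin(x, con, size = size, endian = "little")

  # header: byte order, magic, offset of first IFD (patched later via layout)
  n_pages <- length(pages)
  ifd_entries <- 10L
  ifd_size <- 2L + 12L * ifd_entries + 4L
  # layout: 8-byte header, then per page [pixel data][IFD]
  data_bytes <- vapply(pages, function(p) 4L * length(p), integer(1))
  offsets <- 8L
  page_data_off <- integer(n_pages)
  page_ifd_off <- integer(n_pages)
  for (i in seq_len(n_pages)) {
    page_data_off[i] <- offsets
    page_ifd_off[i] <- offsets + data_bytes[i]
    offsets <- page_ifd_off[i] + ifd_size
  }

  writeChar("II", con, nchars = 2, eos = NULL)
  w(42L, size = 2)
  w(page_ifd_off[1], size = 4)

  entry <- function(tag, type, count, value) {
    w(as.integer(tag), size = 2)
    w(as.integer(type), size = 2)   # 3 = SHORT, 4 = LONG
    w(as.integer(count), size = 4)
    if (type == 3L) {               # SHORT, left-justified in 4-byte field
      w(as.integer(value), size = 2)
      w(0L, size = 2)
    } else {
      w(as.integer(value), size = 4)
    }
  }

  for (i in seq_len(n_pages)) {
    p <- pages[[i]]
    # strip data, row-major (TIFF rows = matrix rows)
    w(as.numeric(t(p)), size = 4)
    # IFD
    w(ifd_entries, size = 2)
    entry(256L, 4L, 1L, ncol(p))            # ImageWidth
    entry(257L, 4L, 1L, nrow(p))            # ImageLength
    entry(258L, 3L, 1L, 32L)                # BitsPerSample
    entry(259L, 3L, 1L, 1L)                 # Compression: none
    entry(262L, 3L, 1L, 1L)                 # Photometric: BlackIsZero
    entry(273L, 4L, 1L, page_data_off[i])   # StripOffsets
    entry(277L, 3L, 1L, 1L)                 # SamplesPerPixel
    entry(278L, 4L, 1L, nrow(p))            # RowsPerStrip
    entry(279L, 4L, 1L, data_bytes[i])      # StripByteCounts
    entry(339L, 3L, 1L, 3L)                 # SampleFormat: IEEE float
    w(if (i < n_pages) page_ifd_off[i + 1] else 0L, size = 4)
  }
  invisible(path)
}

# Round doubles to the nearest float32 value (as the TIFF storage will).
# Note as.single() only tags a vector; actual conversion needs the byte trip.
float32_snap <- function(x) {
  out <- readBin(writeBin(as.numeric(x), raw(), size = 4, endian = "little"),
                 "numeric", n = length(x), size = 4, endian = "little")
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

# Read a float TIFF stack (written here or elsewhere) into a 3-D array
# (page, row, col); values come back as doubles holding exact float32.
read_float_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  arr
}
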