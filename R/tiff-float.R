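# Minimal float32 TIFF writer.
#
# The codec used for integer samples stores real data normalized to [0,1]
# as scaled integers, which cannot represent arbitrary float samples. This
# writer emits baseline little-endian TIFF with SampleFormat = IEEE float,
# 32 bits per sample, one strip per page, uncompressed — exactly the layout
# readTIFF() decodes bit for bit, giving lossless f32 round trips at any
# value range.

tiff_f32_entry <- function(tag, type, count, value) {
  # type 3 = SHORT, 4 = LONG; values fitting 4 bytes are stored inline
  v <- raw(4)
  if (type == 3) {
    v[1:2] <- writeBin(as.integer(value), raw(), size = 2,
                       endian = "little")
  } else {
    v <- writeBin(as.integer(value), raw(), size = 4, endian = "little")
  }
  c(writeBin(as.integer(tag), raw(), size = 2, endian = "little"),
    writeBin(as.integer(type), raw(), size = 2, endian = "little"),
    writeBin(as.integer(count), raw(), size = 4, endian = "little"),
    v)
}

# pages: list of (x, y) arrays; samples are written row-major per page
write_tiff_f32 <- function(pages, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(as.integer(42), con, size = 2, endian = "little")
  # first IFD comes after the 8-byte header and the first page's pixel data
  first_ifd <- 8 + 4 * length(pages[[1]])
  writeBin(as.integer(first_ifd), con, size = 4, endian = "little")
  offset <- 8
  n_pages <- length(pages)
  for (i in seq_len(n_pages)) {
    A <- pages[[i]]
    w <- dim(A)[1]; h <- dim(A)[2]
    nbytes <- 4 * w * h
    data_off <- offset
    ifd_off <- data_off + nbytes
    writeBin(as.double(as.vector(A)), con, size = 4, endian = "little")
    entries <- list(
      tiff_f32_entry(256, 4, 1, w),        # ImageWidth
      tiff_f32_entry(257, 4, 1, h),        # ImageLength
      tiff_f32_entry(258, 3, 1, 32),       # BitsPerSample
      tiff_f32_entry(259, 3, 1, 1),        # Compression: none
      tiff_f32_entry(262, 3, 1, 1),        # Photometric: black is zero
      tiff_f32_entry(273, 4, 1, data_off), # StripOffsets
      tiff_f32_entry(277, 3, 1, 1),        # SamplesPerPixel
      tiff_f32_entry(278, 4, 1, h),        # RowsPerStrip
      tiff_f32_entry(279, 4, 1, nbytes),   # StripByteCounts
      tiff_f32_entry(339, 3, 1, 3))        # SampleFormat: IEEE float
    writeBin(as.integer(length(entries)), con, size = 2, endian = "little")
    for (e in entries) writeBin(e, con)
    ifd_size <- 2 + 12 * length(entries) + 4
    # each page is laid out as [pixel data][IFD]
    next_ifd <- if (i < n_pages)
      ifd_off + ifd_size + 4 * length(pages[[i + 1]]) else 0
    writeBin(as.integer(next_ifd), con, size = 4, endian = "little")
    offset <- ifd_off + ifd_size
  }
  invisible(path)
}
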