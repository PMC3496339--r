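#' Raster image input / output
#'
#' TIFF is the canonical interchange format: single-sample pages of 8 or 16
#' bits (read as `u8` / `u16`) or 32-bit float (read as `f32`); a
#' multi-page file becomes a 3-D image with dims `(width, height, pages)`.
#' PNG is limited to 2-D: 8-bit grayscale (`u8`) and RGBA (`argb`).
#' Axis order is `(x, y[, page])` with x varying fastest, matching the
#' raster order of the flat backends.
#'
#' Float TIFF pages are written by a small built-in writer (baseline
#' uncompressed TIFF with IEEE-float sample format), because the codec used
#' for integer samples only stores reals as scaled integers in `[0, 1]`.
#' `f32` round trips are bitwise exact at any value range; `f64` images are
#' quantized to float32 on write.
#'
#' @name image-io
NULL

file_ext <- function(path) tolower(sub(".*\\.", "", path))

#' Read a raster image
#' @param path a `.tif`/`.tiff` or `.png` file
#' @param factory backend for the pixels; the value type is taken from the
#'   file, overriding the factory's
#' @return an image
#' @export
read_image <- function(path, factory = image_factory("array", "f64")) {
  if (!file.exists(path)) nd_stop("'", path, "': no such file")
  switch(file_ext(path),
    tif = , tiff = read_tiff_image(path, factory),
    png = read_png_image(path, factory),
    nd_stop("'", path, "': unsupported format '.", file_ext(path),
            "' (expected TIFF or PNG)"))
}

read_tiff_image <- function(path, factory) {
  info <- tiff::readTIFF(path, payload = FALSE, all = TRUE)
  bits <- unique(info$bits.per.sample)
  spp <- unique(info$samples.per.pixel)
  if (length(bits) != 1 || length(spp) != 1 ||
      length(unique(info$width)) != 1 || length(unique(info$length)) != 1)
    nd_stop("'", path, "': pages differ in size or sample layout; ",
            "expected a homogeneous stack")
  if (spp != 1)
    nd_stop("'", path, "': ", spp, " samples per pixel; only single-sample ",
            "TIFF is supported (use PNG for RGBA)")
  type <- switch(as.character(bits),
    "8" = "u8", "16" = "u16", "32" = "f32",
    nd_stop("'", path, "': unsupported bit depth ", bits,
            " (expected 8, 16 or 32)"))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = type != "f32")
  if (!is.list(pages)) pages <- list(pages)
  w <- ncol(pages[[1]]); h <- nrow(pages[[1]])
  dims <- if (length(pages) > 1) c(w, h, length(pages)) else c(w, h)
  factory$type <- type
  img <- create_image(factory, dims)
  v <- unlist(lapply(pages, function(m) as.vector(t(m))), use.names = FALSE)
  write_raster_values(img, v)
  img
}

read_png_image <- function(path, factory) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 2) {
    factory$type <- "u8"
    img <- create_image(factory, c(ncol(m), nrow(m)))
    write_raster_values(img, as.vector(t(round(m * 255))))
  } else if (dim(m)[3] %in% c(3, 4)) {
    ch <- function(i) if (i <= dim(m)[3]) as.vector(t(round(m[, , i] * 255)))
      else rep(255, prod(dim(m)[1:2]))
    factory$type <- "argb"
    img <- create_image(factory, c(ncol(m), nrow(m)))
    write_raster_values(img, argb_pack_many(ch(4), ch(1), ch(2), ch(3)))
  } else {
    nd_stop("'", path, "': ", dim(m)[3], "-channel PNG not supported ",
            "(expected grayscale, RGB or RGBA)")
  }
  img
}

#' Write a raster image
#'
#' TIFF accepts `u8`, `u16` and real types (written as 32-bit IEEE float),
#' in 2-D or 3-D (pages along dimension 3). PNG accepts 2-D `u8` and
#' `argb`.
#' @param img a bounded image or view
#' @param path destination; the extension selects the format
#' @export
write_image <- function(img, path) {
  switch(file_ext(path),
    tif = , tiff = write_tiff_image(img, path),
    png = write_png_image(img, path),
    nd_stop("'", path, "': unsupported format '.", file_ext(path),
            "' (expected TIFF or PNG)"))
  invisible(path)
}

write_tiff_image <- function(img, path) {
  n <- img_ndim(img)
  if (!n %in% c(2, 3))
    nd_stop("'", path, "': TIFF output needs a 2-D or 3-D image, got ", n,
            "-D")
  A <- materialize(img)
  type <- img_type(img)
  if (type %in% c("f32", "f64")) {
    pages <- if (n == 2) list(A)
      else lapply(seq_len(dim(A)[3]), function(z) A[, , z])
    return(write_tiff_f32(pages, path))
  }
  prep <- switch(type,
    u8 = list(A / 255, 8L),
    u16 = list(A / 65535, 16L),
    nd_stop("'", path, "': value type '", type,
            "' has no TIFF representation (expected u8, u16, f32 or f64)"))
  to_page <- function(M) t(M)   # (x, y) -> row-major (y, x)
  what <- if (n == 2) to_page(prep[[1]])
    else lapply(seq_len(dim(A)[3]), function(z) to_page(prep[[1]][, , z]))
  tiff::writeTIFF(what, path, bits.per.sample = prep[[2]], reduce = FALSE)
  invisible(path)
}

write_png_image <- function(img, path) {
  if (img_ndim(img) != 2)
    nd_stop("'", path, "': PNG output is 2-D only")
  A <- materialize(img)
  type <- img_type(img)
  if (type == "u8") {
    png::writePNG(t(A) / 255, path)
  } else if (type == "argb") {
    ch <- argb_unpack_many(as.vector(A))
    arr <- array(0, c(dim(A)[2], dim(A)[1], 4))
    arr[, , 1] <- t(array(ch$r, dim(A)))
    arr[, , 2] <- t(array(ch$g, dim(A)))
    arr[, , 3] <- t(array(ch$b, dim(A)))
    arr[, , 4] <- t(array(ch$a, dim(A)))
    png::writePNG(arr / 255, path)
  } else {
    nd_stop("'", path, "': value type '", type,
            "' has no PNG representation (expected u8 or argb)")
  }
  invisible(path)
}
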