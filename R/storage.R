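#' Pixel-image storage backends
#'
#' Three interchangeable representations store the samples of a bounded
#' discrete image:
#' \describe{
#'   \item{array}{one flat primitive buffer in raster order (dimension 1
#'     fastest). Optimal access, but limited to 2^31 elements — the limit a
#'     flat 32-bit-indexed buffer imposes, enforced here for reproducible
#'     capacity behaviour even where the host would allow more (lift with
#'     `options(ndimg.array_capacity = Inf)`).}
#'   \item{cell}{the domain is tiled into an n-dimensional grid of cells,
#'     each backed by its own flat buffer; border cells are truncated. This
#'     lifts the single-buffer limit to at least 2^62 addressable pixels.}
#'   \item{list}{one independent value object per coordinate; supports
#'     arbitrary value types at a large per-pixel cost.}
#' }
#' A factory carries the backend choice so that generic code can create
#' images without knowing the representation.
#'
#' @name storage-backends
NULL

new_buffer <- function(type, n) {
  info <- nd_type_info(type)
  nd_count_pixels(n)
  vector(info$storage, n)
}

#' Raster-order linear index
#'
#' Maps a 0-based coordinate to its 0-based flat-buffer offset:
#' `pos[1] + dims[1]*(pos[2] + dims[2]*(pos[3] + ...))`. Bijective onto
#' `0 .. prod(dims)-1`.
#' @param pos 0-based integer coordinate vector
#' @param dims side lengths
#' @return the 0-based linear index (double, exact below 2^53)
#' @export
linear_index <- function(pos, dims) {
  if (length(pos) != length(dims) || any(pos < 0) || any(pos >= dims))
    nd_stop("linear_index: position out of bounds for dims [",
            paste(dims, collapse = ","), "]")
  idx <- 0
  for (d in rev(seq_along(dims))) idx <- idx * dims[d] + pos[d]
  idx
}

#' @rdname linear_index
#' @param idx a 0-based linear index
#' @return `linear_index_inverse`: the 0-based coordinate vector
#' @export
linear_index_inverse <- function(idx, dims) {
  if (idx < 0 || idx >= prod(dims))
    nd_stop("linear_index_inverse: index out of range")
  pos <- numeric(length(dims))
  for (d in seq_along(dims)) {
    pos[d] <- idx %% dims[d]
    idx <- idx %/% dims[d]
  }
  pos
}

# vectorized: P is k x n of 0-based coords -> k 0-based indices
linear_index_many <- function(P, dims) {
  idx <- numeric(nrow(P))
  mult <- 1
  for (d in seq_along(dims)) {
    idx <- idx + P[, d] * mult
    mult <- mult * dims[d]
  }
  idx
}

#' Image factories
#'
#' A factory bundles a backend tag, a value type and (for the cell backend)
#' the cell dimensions, so algorithms can create output images with
#' identical access semantics regardless of representation.
#'
#' @param backend one of `"array"`, `"cell"`, `"list"`
#' @param type a value-type tag (see [nd_types()])
#' @param cell_dims cell side lengths for the cell backend; recycled over
#'   dimensions. Default 64 per dimension.
#' @return an object of class `nd_factory`
#' @examples
#' f <- image_factory("cell", "u8", cell_dims = c(4, 4))
#' img <- create_image(f, c(10, 10))
#' @export
image_factory <- function(backend = c("array", "cell", "list"), type = "f64",
                          cell_dims = 64) {
  backend <- match.arg(backend)
  nd_type_info(type)
  structure(list(backend = backend, type = type,
                 cell_dims = as.numeric(cell_dims)),
            class = "nd_factory")
}

#' Create a zero-initialized image
#'
#' The result has `min = 0`, `max = dims - 1` and identical read/write
#' behaviour whichever backend produced it.
#' @param factory an [image_factory()]
#' @param dims positive integer side lengths
#' @return an image (class `nd_img`)
#' @export
create_image <- function(factory, dims) {
  iv <- interval_from_dims(dims)
  switch(factory$backend,
    array = new_array_img(iv, factory$type),
    cell  = new_cell_img(iv, factory$type, factory$cell_dims),
    list  = new_list_img(iv, factory$type))
}

new_img <- function(subclass, interval, type, e) {
  structure(list(interval = interval, type = type, e = e),
            class = c(subclass, "nd_img"))
}

new_array_img <- function(interval, type) {
  n <- num_elements(interval)
  if (n > nd_array_capacity())
    nd_stop("array backend cannot hold ", format(n), " samples (flat-buffer ",
            "capacity ", format(nd_array_capacity()), "); use the cell ",
            "backend for images this large")
  e <- new.env(parent = emptyenv())
  e$data <- new_buffer(type, n)
  img <- new_img("nd_array_img", interval, type, e)
  img$dims <- interval_dims(interval)
  img
}

new_cell_img <- function(interval, type, cell_dims) {
  dims <- interval_dims(interval)
  cell_dims <- rep_len(as.numeric(cell_dims), length(dims))
  if (any(cell_dims < 1)) nd_stop("cell_dims must be >= 1")
  if (prod(cell_dims) > nd_array_capacity())
    nd_stop("a single cell may not exceed the flat-buffer capacity")
  grid_dims <- ceiling(dims / cell_dims)
  n_cells <- prod(grid_dims)
  cells <- vector("list", n_cells)
  cdims <- vector("list", n_cells)
  G <- interval_coords(interval_from_dims(grid_dims))
  for (ci in seq_len(n_cells)) {
    cd <- pmin(cell_dims, dims - G[ci, ] * cell_dims)
    cdims[[ci]] <- cd
    cells[[ci]] <- new_buffer(type, prod(cd))
  }
  e <- new.env(parent = emptyenv())
  e$cells <- cells
  img <- new_img("nd_cell_img", interval, type, e)
  img$dims <- dims
  img$cell_dims <- cell_dims
  img$grid_dims <- grid_dims
  img$cdims <- cdims
  img
}

new_list_img <- function(interval, type) {
  n <- num_elements(interval)
  zero <- nd_type_info(type)$zero
  nd_count_pixels(n)
  e <- new.env(parent = emptyenv())
  e$samples <- rep(list(zero), n)
  img <- new_img("nd_list_img", interval, type, e)
  img$dims <- interval_dims(interval)
  img
}

#' Largest square side a flat buffer can hold
#'
#' The largest `L` with `L*L <= capacity`. For the 2^31 flat-buffer limit
#' this is 46,340 pixels per side.
#' @param capacity buffer capacity in elements (>= 1)
#' @export
max_square_side <- function(capacity) {
  if (capacity < 1) nd_stop("capacity must be >= 1")
  L <- floor(sqrt(capacity))
  while ((L + 1)^2 <= capacity) L <- L + 1
  while (L^2 > capacity) L <- L - 1
  L
}

#' Addressable pixel count of cell storage
#'
#' Cell storage addresses a pixel through a cell index and a within-cell
#' offset, each a flat-buffer index, so the grid may hold up to 2^31 cells
#' of up to `max_cell_elements` samples; the product is additionally capped
#' by the global pixel-index width (`index_bits`). With 2^31-element cells
#' and a 63-bit positive index this reports at least 2^62 pixels.
#' @param max_cell_elements largest per-cell element count (default 2^31)
#' @param index_bits width of the global pixel index (63 = positive range
#'   of a signed 64-bit integer)
#' @return addressable pixel count (double; exact for powers of two)
#' @export
cell_capacity_pixels <- function(max_cell_elements = 2^31, index_bits = 63) {
  min(max_cell_elements * 2^31, 2^index_bits)
}

## ---- basic image properties ----------------------------------------------

#' Image properties
#' @param img an image
#' @return `img_interval`: the bounding `nd_interval` (error if unbounded);
#'   `img_type`: the value-type tag; `img_ndim`: dimensionality;
#'   `img_is_bounded`: logical.
#' @export
img_interval <- function(img) {
  if (is.null(img$interval))
    nd_stop("image is unbounded; it has no interval")
  img$interval
}

#' @rdname img_interval
#' @export
img_type <- function(img) img$type

#' @rdname img_interval
#' @export
img_ndim <- function(img) UseMethod("img_ndim")

#' @export
img_ndim.nd_img <- function(img) {
  if (!is.null(img$interval)) interval_ndim(img$interval) else img$n
}

#' @rdname img_interval
#' @export
img_is_bounded <- function(img) !is.null(img$interval)

#' @export
print.nd_img <- function(x, ...) {
  cat("<", class(x)[1], "> type ", x$type, sep = "")
  if (img_is_bounded(x)) {
    cat(", dims ", paste(interval_dims(x$interval), collapse = "x"),
        ", min [", paste(x$interval$min, collapse = ","), "]", sep = "")
  } else cat(", unbounded")
  cat("\n")
  invisible(x)
}
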