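#' Accessors: random access and cursors
#'
#' Two access patterns are distinguished. A \emph{random access} is
#' positioned at arbitrary integer coordinates; a \emph{cursor} visits every
#' sample of a bounded image exactly once, in an order specialized to the
#' memory layout, and can report its current coordinate (`localize`). Both
#' read and write through a single re-positioned \emph{proxy} rather than
#' allocating a value object per sample.
#'
#' Bounds are checked by default; `options(ndimg.checked = FALSE)` disables
#' the check for inner loops (out-of-range access is then undefined).
#'
#' @name accessors
NULL

bounds_checked <- function() isTRUE(getOption("ndimg.checked", TRUE))

check_pos <- function(img, pos) {
  if (bounds_checked() && img_is_bounded(img) &&
      !interval_contains(img$interval, pos))
    nd_stop("position [", paste(pos, collapse = ","),
            "] out of bounds for interval [",
            paste(img$interval$min, collapse = ","), "]..[",
            paste(img$interval$max, collapse = ","), "]")
}

#' Read / write one sample
#'
#' `img_get` returns the raw sample value stored at `pos` (a plain scalar;
#' complex for `"cf32"`); `img_set` writes a value, canonicalized to the
#' image's type semantics (wrap-around etc.). Writing through a view
#' propagates to the view's source.
#' @param img an image or view
#' @param pos integer coordinate vector (0-based)
#' @param value raw value or `nd_value`
#' @export
img_get <- function(img, pos) UseMethod("img_get")

#' @rdname img_get
#' @export
img_set <- function(img, pos, value) UseMethod("img_set")

#' Bulk access: read many samples at once
#'
#' Reads the samples at the rows of `P` through the generic access layer
#' (coordinates are assumed in-bounds of the respective source). This is
#' the vectorized work-horse behind [materialize()], iteration and the
#' algorithms module.
#' @param img an image or view
#' @param P a k x n matrix of coordinates
#' @return a vector of k raw values
#' @export
img_get_many <- function(img, P) UseMethod("img_get_many")

## ---- array backend --------------------------------------------------------

array_offset <- function(img, pos) {
  p0 <- pos - img$interval$min
  idx <- 0
  dims <- img$dims
  for (d in rev(seq_along(dims))) idx <- idx * dims[d] + p0[d]
  idx + 1
}

#' @export
img_get.nd_array_img <- function(img, pos) {
  check_pos(img, pos)
  img$e$data[[array_offset(img, pos)]]
}

#' @export
img_set.nd_array_img <- function(img, pos, value) {
  check_pos(img, pos)
  if (inherits(value, "nd_value")) value <- value$value
  img$e$data[[array_offset(img, pos)]] <- type_wrap(img$type, value)
  invisible(img)
}

#' @export
img_get_many.nd_array_img <- function(img, P) {
  P0 <- sweep(P, 2, img$interval$min)
  img$e$data[linear_index_many(P0, img$dims) + 1]
}

## ---- cell backend ---------------------------------------------------------

cell_locate <- function(img, pos) {
  p0 <- pos - img$interval$min
  ci <- p0 %/% img$cell_dims
  within <- p0 %% img$cell_dims
  cell <- linear_index(ci, img$grid_dims) + 1
  list(cell = cell, off = linear_index(within, img$cdims[[cell]]) + 1)
}

#' @export
img_get.nd_cell_img <- function(img, pos) {
  check_pos(img, pos)
  loc <- cell_locate(img, pos)
  img$e$cells[[loc$cell]][[loc$off]]
}

#' @export
img_set.nd_cell_img <- function(img, pos, value) {
  check_pos(img, pos)
  if (inherits(value, "nd_value")) value <- value$value
  loc <- cell_locate(img, pos)
  img$e$cells[[loc$cell]][[loc$off]] <- type_wrap(img$type, value)
  invisible(img)
}

#' @export
img_get_many.nd_cell_img <- function(img, P) {
  P0 <- sweep(P, 2, img$interval$min)
  CI <- P0 %/% matrix(img$cell_dims, nrow(P0), ncol(P0), byrow = TRUE)
  W <- P0 - CI * matrix(img$cell_dims, nrow(P0), ncol(P0), byrow = TRUE)
  cell_id <- linear_index_many(CI, img$grid_dims) + 1
  out <- vector(nd_type_info(img$type)$storage, nrow(P))
  for (cid in unique(cell_id)) {
    sel <- cell_id == cid
    off <- linear_index_many(W[sel, , drop = FALSE], img$cdims[[cid]]) + 1
    out[sel] <- img$e$cells[[cid]][off]
  }
  out
}

## ---- list backend ---------------------------------------------------------

#' @export
img_get.nd_list_img <- function(img, pos) {
  check_pos(img, pos)
  img$e$samples[[array_offset(img, pos)]]
}

#' @export
img_set.nd_list_img <- function(img, pos, value) {
  check_pos(img, pos)
  if (inherits(value, "nd_value")) value <- value$value
  img$e$samples[[array_offset(img, pos)]] <- type_wrap(img$type, value)
  invisible(img)
}

#' @export
img_get_many.nd_list_img <- function(img, P) {
  P0 <- sweep(P, 2, img$interval$min)
  idx <- linear_index_many(P0, img$dims) + 1
  v <- unlist(img$e$samples[idx], use.names = FALSE)
  if (nd_type_info(img$type)$storage == "complex") v <- as.complex(v)
  v
}

## ---- iteration ------------------------------------------------------------

#' Iteration order descriptor
#'
#' Two images may be co-iterated sample-aligned only when their descriptors
#' are equal; the flat backends (array, list, all bounded views) share flat
#' raster order while the cell backend iterates cell-by-cell.
#' @param img a bounded image
#' @return a list with elements `kind` (`"flat"` or `"cell"`), `dims` and,
#'   for cell images, `cell_dims`
#' @export
iteration_order <- function(img) UseMethod("iteration_order")

#' @export
iteration_order.nd_img <- function(img) {
  if (!img_is_bounded(img)) nd_stop("unbounded images are not iterable")
  list(kind = "flat", dims = interval_dims(img$interval))
}

#' @export
iteration_order.nd_cell_img <- function(img) {
  list(kind = "cell", dims = img$dims, cell_dims = img$cell_dims)
}

#' @rdname iteration_order
#' @param a,b iteration-order descriptors (or images, which are converted)
#' @export
iteration_order_equal <- function(a, b) {
  if (inherits(a, "nd_img")) a <- iteration_order(a)
  if (inherits(b, "nd_img")) b <- iteration_order(b)
  identical(a$kind, b$kind) && length(a$dims) == length(b$dims) &&
    all(a$dims == b$dims) &&
    (a$kind != "cell" || all(a$cell_dims == b$cell_dims))
}

#' Coordinates / values of a full iteration
#'
#' `img_coords` enumerates every coordinate of the domain in the image's
#' iteration order; `img_values` returns the samples in the same order;
#' `iterate` returns both. Array and list backends (and bounded views) use
#' flat raster order, dimension 1 fastest; the cell backend visits cells in
#' raster order of the cell grid and samples in raster order within each
#' cell.
#' @param img a bounded image or view
#' @return `img_coords`: an `num_elements` by `ndim` matrix; `img_values`:
#'   a vector; `iterate`: `list(coords=, values=)`
#' @export
img_coords <- function(img) UseMethod("img_coords")

#' @export
img_coords.nd_img <- function(img) interval_coords(img_interval(img))

#' @export
img_coords.nd_cell_img <- function(img) {
  G <- interval_coords(interval_from_dims(img$grid_dims))
  out <- vector("list", nrow(G))
  for (ci in seq_len(nrow(G))) {
    origin <- img$interval$min + G[ci, ] * img$cell_dims
    cc <- interval_coords(interval_from_dims(img$cdims[[ci]]))
    out[[ci]] <- sweep(cc, 2, origin, `+`)
  }
  do.call(rbind, out)
}

#' @rdname img_coords
#' @export
img_values <- function(img) UseMethod("img_values")

#' @export
img_values.nd_img <- function(img) img_get_many(img, img_coords(img))

#' @export
img_values.nd_array_img <- function(img) img$e$data

#' @export
img_values.nd_cell_img <- function(img) {
  do.call(c, img$e$cells)
}

#' @export
img_values.nd_list_img <- function(img) {
  v <- unlist(img$e$samples, use.names = FALSE)
  if (nd_type_info(img$type)$storage == "complex") v <- as.complex(v)
  v
}

#' @rdname img_coords
#' @export
iterate <- function(img) {
  if (!img_is_bounded(img)) nd_stop("unbounded images are not iterable")
  list(coords = img_coords(img), values = img_values(img))
}

#' Bulk write in the image's iteration order
#' @param img an image or writable view
#' @param values vector of raw values, one per sample, in iteration order
#' @export
img_write_values <- function(img, values) UseMethod("img_write_values")

#' @export
img_write_values.nd_array_img <- function(img, values) {
  stopifnot(length(values) == length(img$e$data))
  img$e$data <- type_wrap(img$type, values)
  invisible(img)
}

#' @export
img_write_values.nd_cell_img <- function(img, values) {
  values <- type_wrap(img$type, values)
  at <- 0
  for (ci in seq_along(img$e$cells)) {
    k <- length(img$e$cells[[ci]])
    img$e$cells[[ci]] <- values[(at + 1):(at + k)]
    at <- at + k
  }
  invisible(img)
}

#' @export
img_write_values.nd_list_img <- function(img, values) {
  img$e$samples <- as.list(type_wrap(img$type, values))
  invisible(img)
}

#' @export
img_write_values.nd_img <- function(img, values) {
  # generic fall-back for writable views: per-sample writes in iteration order
  P <- img_coords(img)
  for (i in seq_len(nrow(P))) img_set(img, P[i, ], values[[i]])
  invisible(img)
}

## ---- materialization bridges ---------------------------------------------

#' Materialize an image (or view) into a plain R array
#'
#' Reads every sample through the generic access layer, so the result is
#' identical whichever backend or view composition produced the samples.
#' The first array index corresponds to dimension 1 of the image.
#' @param img an image or view
#' @param interval the region to read; defaults to the image's interval
#'   (required for unbounded images)
#' @return an R array with `dim = interval_dims(interval)`
#' @export
materialize <- function(img, interval = NULL) {
  if (is.null(interval)) interval <- img_interval(img)
  v <- img_get_many(img, interval_coords(interval))
  array(v, dim = interval_dims(interval))
}

#' Build an image from a plain R array
#' @param arr an R array (or vector with `dim`)
#' @param factory an [image_factory()] giving backend and value type
#' @return an image with dims `dim(arr)` in raster correspondence
#' @export
image_from_array <- function(arr, factory = image_factory("array", "f64")) {
  d <- dim(arr)
  if (is.null(d)) d <- length(arr)
  img <- create_image(factory, d)
  write_raster_values(img, as.vector(arr))
  img
}

# Bulk write of values given in raster order (dimension 1 fastest),
# regardless of the image's own iteration order.
write_raster_values <- function(img, values) {
  dims <- interval_dims(img_interval(img))
  P <- sweep(img_coords(img), 2, img_interval(img)$min)
  img_write_values(img, values[linear_index_many(P, dims) + 1])
}

## ---- proxies --------------------------------------------------------------

#' Value proxies
#'
#' A proxy is a mutable handle onto one sample inside backing storage. It is
#' created once per accessor and re-positioned per access: repositioning
#' changes only internal state and never allocates. A proxy is a \emph{live}
#' handle — after the owning cursor advances it refers to the new sample;
#' [proxy_snapshot()] takes a boxed copy that survives.
#' @param img the backing image
#' @return an environment of class `nd_proxy`
#' @export
new_proxy <- function(img) {
  p <- new.env(parent = emptyenv())
  p$img <- img
  p$pos <- NULL
  class(p) <- "nd_proxy"
  p
}

#' @rdname new_proxy
#' @param proxy an `nd_proxy`
#' @export
proxy_value <- function(proxy) img_get(proxy$img, proxy$pos)

#' @rdname new_proxy
#' @param value raw value to store at the proxy's position
#' @export
proxy_write <- function(proxy, value) img_set(proxy$img, proxy$pos, value)

#' @rdname new_proxy
#' @return `proxy_snapshot`: an [nd_value()] copy of the current sample
#' @export
proxy_snapshot <- function(proxy) nd_value(proxy_value(proxy),
                                           img_type(proxy$img))

## ---- random access ---------------------------------------------------------

#' Create a random access on an image
#'
#' The access holds one proxy; [ra_set_pos()] re-positions it (cost
#' independent of distance for flat layouts) and [ra_get()]/[ra_set()] read
#' and write the sample under it.
#' @param img an image or view
#' @return an environment of class `nd_random_access`
#' @examples
#' img <- create_image(image_factory("array", "u8"), c(4, 4))
#' ra <- random_access(img)
#' ra_set_pos(ra, c(3, 1)); ra_set(ra, 7)
#' ra_get(ra)
#' @export
random_access <- function(img) {
  ra <- new.env(parent = emptyenv())
  ra$img <- img
  ra$proxy <- new.env(parent = emptyenv())
  ra$proxy$img <- img
  class(ra$proxy) <- "nd_proxy"
  class(ra) <- "nd_random_access"
  ra
}

#' @rdname random_access
#' @param ra an `nd_random_access`
#' @param pos integer coordinate vector
#' @export
ra_set_pos <- function(ra, pos) {
  ra$proxy$pos <- pos
  invisible(ra)
}

#' @rdname random_access
#' @export
ra_get <- function(ra) proxy_value(ra$proxy)

#' @rdname random_access
#' @param value raw value to write
#' @export
ra_set <- function(ra, value) proxy_write(ra$proxy, value)

#' Convenience: positioned read
#' @param img an image or view
#' @param pos coordinate vector
#' @export
random_access_get <- function(img, pos) img_get(img, pos)

## ---- cursors ---------------------------------------------------------------

#' Create a cursor over a bounded image
#'
#' The cursor starts \emph{before} the first sample; [cursor_fwd()] advances
#' it. A full sweep visits every sample exactly once in the image's
#' iteration order. [cursor_localize()] returns a copy of the current
#' coordinate (never a live internal vector). The value handle returned by
#' [cursor_proxy()] is live: it follows the cursor when it advances; use
#' [proxy_snapshot()] for a copy that survives.
#' @param img a bounded image or view
#' @return an environment of class `nd_cursor`
#' @export
cursor <- function(img) {
  if (!img_is_bounded(img)) nd_stop("unbounded images are not iterable")
  cur <- new.env(parent = emptyenv())
  cur$img <- img
  cur$i <- 0
  cur$n <- num_elements(img_interval(img))
  cur$order <- iteration_order(img)
  cur$proxy <- new.env(parent = emptyenv())
  cur$proxy$img <- img
  class(cur$proxy) <- "nd_proxy"
  class(cur) <- "nd_cursor"
  cur
}

cursor_coord_at <- function(cur, i) {
  # i is 1-based progress within the iteration order
  img <- cur$img
  if (cur$order$kind == "cell") {
    # walk cells in grid raster order until the one holding sample i
    j <- i - 1
    for (ci in seq_along(img$cdims)) {
      k <- prod(img$cdims[[ci]])
      if (j < k) {
        G <- linear_index_inverse(ci - 1, img$grid_dims)
        origin <- img$interval$min + G * img$cell_dims
        return(origin + linear_index_inverse(j, img$cdims[[ci]]))
      }
      j <- j - k
    }
    nd_stop("cursor exhausted")
  }
  img_interval(img)$min +
    linear_index_inverse(i - 1, interval_dims(img_interval(img)))
}

#' @rdname cursor
#' @param cur an `nd_cursor`
#' @export
cursor_has_next <- function(cur) cur$i < cur$n

#' @rdname cursor
#' @export
cursor_fwd <- function(cur) {
  if (!cursor_has_next(cur)) nd_stop("cursor exhausted")
  cur$i <- cur$i + 1
  cur$proxy$pos <- cursor_coord_at(cur, cur$i)
  invisible(cur)
}

#' @rdname cursor
#' @export
cursor_localize <- function(cur) {
  if (cur$i == 0) nd_stop("cursor not yet advanced")
  cur$proxy$pos + 0   # forced copy
}

#' @rdname cursor
#' @export
cursor_value <- function(cur) proxy_value(cur$proxy)

#' @rdname cursor
#' @export
cursor_proxy <- function(cur) cur$proxy

#' @rdname cursor
#' @param value raw value to write at the cursor position
#' @export
cursor_set <- function(cur, value) proxy_write(cur$proxy, value)
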