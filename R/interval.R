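#' Integer intervals (bounding boxes)
#'
#' An interval is the discrete coordinate domain of a bounded image: a pair
#' of integer vectors `min`, `max`, both inclusive, one entry per dimension.
#' Coordinates are 0-based; translated views may have negative minima.
#'
#' @param min,max integer vectors of equal length, `min[d] <= max[d]`
#' @return an object of class `nd_interval`
#' @examples
#' iv <- nd_interval(c(0, 0), c(4, 3))   # a 5 x 4 domain
#' interval_dims(iv)
#' @export
nd_interval <- function(min, max) {
  min <- as.numeric(min)
  max <- as.numeric(max)
  if (length(min) != length(max) || length(min) < 1)
    nd_stop("interval: min and max must be non-empty vectors of equal length")
  if (any(max < min))
    nd_stop("interval: max[d] must be >= min[d] for every dimension")
  structure(list(min = min, max = max), class = "nd_interval")
}

#' Interval from dimensions, minimum at the origin
#' @param dims positive integer vector of side lengths
#' @return an `nd_interval` with `min = 0`, `max = dims - 1`
#' @export
interval_from_dims <- function(dims) {
  dims <- as.numeric(dims)
  if (length(dims) < 1 || any(dims < 1) || any(dims != floor(dims)))
    nd_stop("interval: dims must be positive integers")
  nd_interval(rep(0, length(dims)), dims - 1)
}

#' @rdname nd_interval
#' @param x an `nd_interval`
#' @export
interval_dims <- function(x) x$max - x$min + 1

#' @rdname nd_interval
#' @export
interval_ndim <- function(x) length(x$min)

#' Number of samples in an interval
#' @param x an `nd_interval`
#' @return the product of the side lengths (as a double; may exceed 2^31)
#' @export
num_elements <- function(x) prod(interval_dims(x))

#' Does an interval contain a coordinate / another interval?
#' @param x an `nd_interval`
#' @param pos integer coordinate vector
#' @export
interval_contains <- function(x, pos) {
  length(pos) == length(x$min) && all(pos >= x$min) && all(pos <= x$max)
}

#' @rdname interval_contains
#' @param inner an `nd_interval` to test for containment in `x`
#' @export
interval_contains_interval <- function(x, inner) {
  all(inner$min >= x$min) && all(inner$max <= x$max)
}

# rows of P (k x n) inside x -> logical vector of length k
interval_contains_many <- function(x, P) {
  ok <- rep(TRUE, nrow(P))
  for (d in seq_along(x$min))
    ok <- ok & P[, d] >= x$min[d] & P[, d] <= x$max[d]
  ok
}

#' Enumerate all coordinates of an interval in raster order
#'
#' Dimension 1 varies fastest (flat raster order).
#' @param x an `nd_interval`
#' @return a `num_elements(x)` by `ndim` numeric matrix
#' @export
interval_coords <- function(x) {
  dims <- interval_dims(x)
  n <- length(dims)
  k <- prod(dims)
  P <- matrix(0, nrow = k, ncol = n)
  rep_inner <- 1
  for (d in seq_len(n)) {
    P[, d] <- rep(seq.int(x$min[d], x$max[d]),
                  each = rep_inner, length.out = k)
    rep_inner <- rep_inner * dims[d]
  }
  P
}

#' @export
print.nd_interval <- function(x, ...) {
  cat("<nd_interval> [", paste(x$min, collapse = ","), "] .. [",
      paste(x$max, collapse = ","), "]  dims ",
      paste(interval_dims(x), collapse = "x"), "\n", sep = "")
  invisible(x)
}

#' @export
`==.nd_interval` <- function(e1, e2) {
  length(e1$min) == length(e2$min) &&
    all(e1$min == e2$min) && all(e1$max == e2$max)
}
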