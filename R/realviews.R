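#' Continuous-coordinate access
#'
#' Interpolating views lift a discrete image to real coordinates; affine
#' views transform real coordinates lazily; rasterization evaluates a
#' continuous image back onto the integer grid. Grid samples sit at integer
#' coordinates (pixel-center convention) — resampling results differ under
#' a pixel-corner convention, so this choice is part of the contract.
#'
#' @name realviews
NULL

#' Real-coordinate access
#'
#' `real_get` evaluates a continuous image at one real coordinate;
#' `real_get_many` at the rows of a matrix.
#' @param rimg a continuous image (class `nd_real`)
#' @param x real coordinate vector
#' @export
real_get <- function(rimg, x) {
  real_get_many(rimg, matrix(x, nrow = 1))[[1]]
}

#' @rdname real_get
#' @param X a k x n matrix of real coordinates
#' @export
real_get_many <- function(rimg, X) UseMethod("real_get_many")

#' @rdname real_get
#' @export
real_ndim <- function(rimg) rimg$n

#' Procedural continuous image
#'
#' Wraps a closed-form function of real coordinates as an unbounded
#' continuous image (useful as an analytic oracle and for demo inputs).
#' @param fn function taking a k x n coordinate matrix, returning k values
#' @param n dimensionality
#' @export
real_procedural <- function(fn, n) {
  structure(list(fn = fn, n = n), class = c("nd_procedural", "nd_real"))
}

#' @export
real_get_many.nd_procedural <- function(rimg, X) rimg$fn(X)

## ---- interpolation ---------------------------------------------------------

#' Interpolate a discrete image to real coordinates
#'
#' \describe{
#'   \item{nearest}{value of the grid point obtained by rounding each
#'     coordinate half-up (ties `x.5` round toward +inf) — deterministic}
#'   \item{nlinear}{convex combination of the `2^n` grid samples
#'     surrounding the query, with weights `prod_d(1 - |x_d - g_d|)`; at
#'     exact grid coordinates this returns the grid sample}
#' }
#' Extend the source first if queries may leave its interval.
#' @param img a discrete image or view
#' @param kind `"nearest"` or `"nlinear"`
#' @return a continuous image (class `nd_interp`)
#' @export
interpolate <- function(img, kind = c("nlinear", "nearest")) {
  kind <- match.arg(kind)
  structure(list(source = img, kind = kind, n = img_ndim(img)),
            class = c("nd_interp", "nd_real"))
}

#' @export
real_get_many.nd_interp <- function(rimg, X) {
  if (rimg$kind == "nearest")
    return(img_get_many(rimg$source, floor(X + 0.5)))
  n <- ncol(X)
  base <- floor(X)
  f <- X - base
  out <- numeric(nrow(X))
  for (corner in 0:(2^n - 1)) {
    bits <- as.numeric(bitwAnd(corner, 2^(seq_len(n) - 1)) > 0)
    W <- rep(1, nrow(X))
    for (d in seq_len(n))
      W <- W * (if (bits[d] == 1) f[, d] else 1 - f[, d])
    hit <- W > 0
    if (any(hit)) {
      G <- sweep(base[hit, , drop = FALSE], 2, bits, `+`)
      out[hit] <- out[hit] + W[hit] * img_get_many(rimg$source, G)
    }
  }
  out
}

## ---- affine transforms -----------------------------------------------------

#' N-dimensional affine transforms
#'
#' `y = m %*% x + t`. `affine_compose(A, B)` applies `B` first, then `A`
#' (function-composition order, as in matrix products).
#' @param m an n x n matrix
#' @param t translation vector of length n
#' @return an object of class `nd_affine`
#' @export
nd_affine <- function(m, t = rep(0, nrow(m))) {
  m <- as.matrix(m)
  stopifnot(nrow(m) == ncol(m), length(t) == nrow(m))
  structure(list(m = m, t = as.numeric(t), n = nrow(m)), class = "nd_affine")
}

#' @rdname nd_affine
#' @param theta rotation angle in radians (counter-clockwise)
#' @export
affine_rotation2d <- function(theta) {
  nd_affine(matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2))
}

#' @rdname nd_affine
#' @param A an `nd_affine`
#' @param X a k x n matrix (or vector) of coordinates
#' @export
affine_apply <- function(A, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  sweep(X %*% t(A$m), 2, A$t, `+`)
}

#' @rdname nd_affine
#' @param B an `nd_affine` applied before `A`
#' @export
affine_compose <- function(A, B) {
  nd_affine(A$m %*% B$m, as.numeric(A$m %*% B$t) + A$t)
}

#' @rdname nd_affine
#' @export
affine_inverse <- function(A) {
  d <- det(A$m)
  if (!is.finite(d) || abs(d) < 1e-12)
    nd_stop("affine transform is singular (determinant ", format(d), ")")
  mi <- solve(A$m)
  nd_affine(mi, as.numeric(-mi %*% A$t))
}

#' Lazy affine view of a continuous image
#'
#' `real_get(view, x)` equals `real_get(cimg, Tinv(x))`: the view shows the
#' source transformed forward by `T`.
#' @param cimg a continuous image
#' @param T an invertible [nd_affine()]
#' @export
affine_view <- function(cimg, T) {
  Tinv <- affine_inverse(T)
  structure(list(source = cimg, tinv = Tinv, n = cimg$n),
            class = c("nd_affine_view", "nd_real"))
}

#' @export
real_get_many.nd_affine_view <- function(rimg, X) {
  real_get_many(rimg$source, affine_apply(rimg$tinv, X))
}

## ---- rasterization ---------------------------------------------------------

#' Rasterize a continuous image onto an integer grid
#'
#' Evaluates the continuous image at every integer coordinate of
#' `interval` and materializes the samples into a new image:
#' `img_get(out, p) == real_get(cimg, p)` for every `p` in the interval.
#' @param cimg a continuous image
#' @param interval the target `nd_interval`
#' @param factory backend/type for the output (default flat f64)
#' @export
rasterize <- function(cimg, interval,
                      factory = image_factory("array", "f64")) {
  v <- real_get_many(cimg, interval_coords(interval))
  out <- create_image(factory, interval_dims(interval))
  img_write_values(out, v)
  if (any(interval$min != 0)) out <- translate(out, interval$min)
  out
}
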